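column	type	units	description
variant	character	-	substitution name, wild-type aa + position + mutant aa (e.g. N370S)
wt_aa	character	-	wild-type amino acid, one-letter code
position	integer	-	author residue number in the structure
mut_aa	character	-	mutant amino acid, one-letter code
ddg	numeric	kcal/mol	externally computed stability change upon mutation; positive destabilizes
binds_ligand	logical	-	any heavy atom of the residue within 5 A (inclusive) of a ligand heavy atom
n_contacts	integer	count	distinct residues in contact with the mutated residue
catalytic_domain	logical	-	position inside a configured catalytic-domain range (inclusive ends)
p_inv	integer	count	inverse-parallel relations: outer contacts containing a contact of this residue
p_par	integer	count	parallel relations: contacts nested inside a contact of this residue
series	integer	count	series relations: contacts disjoint from this residue's contacts
cross	integer	count	cross relations: contacts partially overlapping this residue's contacts
ca_b_factor	numeric	A^2	crystallographic temperature factor of the CA atom; NA when CA missing
responsive	logical	-	assay label: activity increased under chaperone treatment (when supplied)
label_source	character	-	assay / chaperone compound the label refers to (when supplied)
cp_*	integer	count	contacting-residue type profile over the 20 standard aa plus cp_other; sums to n_contacts
pssm_*	integer	log-odds	PSSM row of the position over the 20 standard aa (when a PSSM is supplied)
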