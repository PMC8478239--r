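# chaperesp workflow configuration template
# Relative paths are resolved against this file's directory.

# --- features stage (runFeatures) ---
variants: variants.csv        # required: protein_id, variant, ddg[, label]
structure: protein.pdb        # optional PDB; omit to pass features through
chain: A                      # chain to restrict to (single chain required)
ligand: NND                   # het residue name of the active-site ligand
preset: methods               # contact definition: methods (4.5 A, >=5
                              # pairs) or results (8 A, >=6 pairs)
catalytic_ranges:             # inclusive residue-number intervals of the
  - [30, 400]                 # catalytic domain (user configuration)
# pssm: protein.pssm          # optional PSI-BLAST ASCII PSSM

# --- predict stage (runPredict) ---
features: out/features.csv    # feature table produced by the stage above
# thresholds:                 # optional overrides of the published splits
#   contacts_small: 4
#   pinv_high: 100
# leaf_probs:                 # optional overrides of unprinted leaves
#   mid_ddg: 0.60

# --- kinetics stage (runKinetics) ---
ddg_min: 0
ddg_max: 4
step: 0.05

outdir: out
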