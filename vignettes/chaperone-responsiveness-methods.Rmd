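---
title: "Methods: circuit topology, decision rules and ER kinetics in chaperesp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit topology, decision rules and ER kinetics in chaperesp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaperesp)
```

# The problem

A pathogenic missense variant of a lysosomal enzyme often acts by
destabilizing the fold: the protein is produced, fails ER quality control,
and is degraded, so too little enzyme reaches the lysosome. Pharmacological
chaperones (PCs) — small molecules, typically active-site binders — can
stabilize the folded state in the ER and restore trafficking for *some*
variants. `chaperesp` implements a structure-based triage of variants into
likely responders and non-responders, and a kinetic model of why the
*position of a residue in the folding order* matters for rescuability.

# Contacts and circuit topology

## Contact definition

Residues are in contact when they form at least `min_atom_pairs`
atom–atom pairs within `atom_dist_cutoff` (inclusive) and are at least
`min_seq_sep` apart in sequence. Two presets are shipped because two
parameterizations are in circulation for this analysis family:

| preset | cutoff | min pairs | rationale |
|---|---|---|---|
| `"methods"` (default) | 4.5 Å | 5 | the stated computation for per-residue contact counts |
| `"results"` | 8 Å | 6 | the coarser definition quoted alongside the feature description |

Neither is declared canonical; results in this package are reported under
`"methods"` unless stated. `min_seq_sep = 2` excludes backbone neighbours
(*i*, *i*+1), which would otherwise dominate every contact list; the choice
is ours, stated here once. All distance comparisons package-wide are
inclusive (`<=`), a single convention chosen to make boundary fixtures
deterministic. Hydrogens are parsed but excluded from all distance
computations (`heavy_only = TRUE`); contact counting is about packing, not
protonation. Alternate locations are resolved to the highest-occupancy
conformer, ties toward altloc "A", so geometry is single-valued and
deterministic.

## Relations

The interval of a contact (*i*, *j*) is the sequence span [*i*, *j*]. For
ordered contacts (a, b): **P** when a's interval lies strictly inside b's,
**P⁻¹** when it strictly contains b's (a is the outer contact), **S** when
disjoint, **X** when partially overlapping. Pairs sharing an endpoint are
labelled **concerted** and excluded from the four basic counts: nesting
direction is ill-defined at a shared endpoint, and the worked panels never
depend on such pairs. This makes {S, P/P⁻¹, X} a true partition of
non-endpoint-sharing pairs, which the test suite checks exhaustively.

## Local circuit topology

For residue r, the count for relation R is the number of *distinct*
contacts standing in relation R to at least one contact formed by r,
excluding r's own contacts. Distinct-contact counting (rather than
pair counting) follows the reading of the statistic as "the number of
contacts with a particular relation"; a pair-counting mode
(`count_pairs = TRUE`) is provided for sensitivity analysis since the
original counting convention is not published. Direction: r's P⁻¹ count is
the number of **outer** contacts containing one of r's contacts, so high
P⁻¹ marks residues on inner, presumed early-folding, contacts.

`bruteForceRelations()` re-derives every ordered pair's label through
interval set operations (membership and `setequal`), an independent code
path used as the oracle; `localTopology()` must agree with its aggregation
on 1,000 random maps of up to 12 contacts in the acceptance suite.

# The decision tree

The cascade is encoded as narrated for the published tree, with the ΔΔG
splits 1.7 / 0.94 / −1.4 kcal/mol taken verbatim. Two splits are *not*
printed at full precision anywhere and deserve flags:

- `contacts_small = 4`: the worked panel only constrains the split to
  (3, 5] (a 3-contact variant reaches the responsive leaf, a 5-contact one
  does not); we take the midpoint, configurable.
- `pinv_high = 100`: unprinted; any value in [1, 219] reproduces the
  worked panel. Treat predictions near this node as qualitative. The test
  suite verifies the panel's leaf routing for every `pinv_high` in
  {1, 50, 100, 219} and `contacts_small` in {4, 5}.

Leaf probabilities 0.60 / 0.28 / 0.34 (`small_contacts`, `root_destab`,
`pinv_high`) are published; the remaining four leaves default to the
class-typical value (0.28 or 0.60) and are explicitly overridable —
predictions landing there carry correct labels but synthetic p₁.
Boundary conventions (`>=` at the root, `<=` at the stabilizing branch,
`<` at the mid-ΔΔG branch) cannot be discriminated by the worked panel
(no variant sits on a boundary); the stated set is fixed so behaviour is
deterministic.

# The ER kinetic model

Species: unfolded U, folded F, chaperone-bound F_B, exported E, with

$$\frac{dU}{dt} = P - k_p U - k_f U + k_u F,\qquad
\frac{dF}{dt} = k_f U - (k_u + k_{on}L + k_{out})F + k_{off}F_B,$$
$$\frac{dF_B}{dt} = k_{on}L\,F - (k_{off} + k_{out})F_B,\qquad
\frac{dE}{dt} = k_{out}(F + F_B).$$

The closed-form steady state is derived from this scheme directly (the
published display equation for F is typographically corrupted in available
renderings, so the derivation is cross-validated two ways: against the
intact bound-state identity $F_B(k_{off}+k_{out}) = k_{on}L\,F$ and against
long-time `deSolve::lsoda` integration to $10^{-6}$ relative agreement).
Reference rates: $P = 0.1$, $k_p = 10$, $k_f = 10$, $k_u = 0.01$,
$k_{out} = 0.01$, and $k_{on}L = 0.1$, $k_{off} = 0.01$ with chaperone.
"Without chaperone" is $k_{on}L = k_{off} = 10^{-5}$, matching the stated
parameterization rather than literal zero; a literal-zero path exists and
is tested separately. Units are arbitrary inverse time; only ratios matter.

ΔΔG maps to rates by $\Delta\Delta G = 4.0963 - 0.593\ln(k_f/k_u)$; the
constant is kept verbatim — it zeroes the wild-type reference
($0.593\ln 1000 \approx 4.0963$) to within $10^{-4}$ kcal/mol. A mutation
perturbs exactly one rate: mode `"unfolding"` (φ = 0) solves for $k_u$,
mode `"folding"` (φ = 1) for $k_f$. Fractional φ is out of scope. Degenerate
inputs are rejected rather than patched: negative rates fail class
validity, $k_{on}L > 0$ with $k_{off} + k_{out} = 0$ (bound state without a
sink) and non-positive steady-state denominators raise errors.

The model's prediction — at matched destabilization, the chaperone rescue
ratio is larger in unfolding mode than folding mode — is a property, not a
fitted result; no plotted flux values are published to compare against, so
the package asserts the ordering over a ΔΔG grid rather than numbers.

# Synthetic data

`makeStructure()` builds chains of 5-atom clusters: contacting pairs have
centres 3 Å apart (all 25 atom pairs within 4.5 Å), non-contacting pairs
≥ 15 Å (none within 4.5 Å), so the declared contact set is recovered
*exactly* under the `"methods"` preset, by construction, under the
±0.05 Å seeded jitter. It emulates contact geometry only — no side-chain
chemistry, no realistic packing densities, no B-factor structure — so
passing round-trips demonstrate correctness of the contact/topology code
path, not performance on real crystal structures.

`makeVariantTable()` draws features and labels from a stated logistic
model: $\text{ddg} \sim N(1, 1.5)$ (pathogenic variants skew
destabilizing), $\text{binds\_ligand} \sim \text{Bern}(0.1)$,
$p_{inv} \sim \text{round}(\Gamma(2, 60))$ (mean 120, matching the scale of
the worked panel's counts), and
$\Pr(\text{responsive}) = \text{logit}^{-1}(0.5 - 1.2\,\text{ddg}
- 2\,\text{binds} - 0.01\,p_{inv})$, optional Gaussian logit noise
(default 0). Coefficient signs encode the qualitative findings
(destabilization, ligand contact and high P⁻¹ all reduce rescue);
magnitudes are our choice of a realistic effect scale and reproduce the
observed direction — non-responsive variants have higher mean ΔΔG — at
n = 2,000. A 10,000-row `glm` fit recovers the coefficients within three
standard errors in the test suite. The generator does not emulate
between-protein transfer, label noise from assay thresholds, or feature
correlations (real ΔΔG and contact count co-vary with burial).

# Problem sizes and tolerances

The test suite uses 1,000 random maps (≤ 12 contacts) for the topology
oracle, 100 random positive-rate grids (log-uniform on [0.01, 10]) for
steady-state/ODE agreement at $10^{-6}$ relative, mass balance at
$10^{-10}$, 50-point ΔΔG grids for the rescue ordering, and 2,000/10,000
row variant tables — sizes at which every check is exact or
sampling-stable and the whole suite runs in about a minute per heavy
file. MCC uses the 0-on-zero-denominator convention; AUC is the midrank
Mann–Whitney statistic, cross-checked against the Wilcoxon route.

# Known limitations

- ΔΔG is an input; the package does not compute stability changes and
  inherits any bias of the upstream predictor.
- The `pinv_high` and `contacts_small` splits are under-determined by
  published information (flags above); downstream users should report
  which values they used.
- Catalytic-domain ranges are user configuration; the shipped Gaucher
  panel carries the published membership column instead.
- Recomputing the panel's contact and P⁻¹ counts from the crystal
  structure requires the structure file and a resolution of the
  contact-definition ambiguity, and is deliberately not an automated
  claim of this package.
- The kinetic model is two-state with a single chaperone-bound species;
  multi-state folding, fractional φ and stochastic effects are out of
  scope.
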