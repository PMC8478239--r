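#' @import methods
NULL

#' Parsed protein structure
#'
#' Holds one parsed atomic model: polymer atoms and het-group atoms with
#' coordinates, occupancies, B-factors and element symbols, after alternate
#' locations have been resolved to a single conformer (highest occupancy,
#' ties broken toward altloc "A"). Hydrogens are retained but flagged; all
#' distance computations downstream use heavy atoms only.
#'
#' @slot atoms data.frame with one row per atom and columns `type`
#'   ("ATOM"/"HETATM"), `eleno`, `elety` (atom name), `resid` (residue name),
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy` (element),
#'   `is_heavy` (logical).
#' @slot source character, path the structure was read from.
#'
#' @seealso [readPDB()], [caBFactor()], [ligandAtoms()]
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", source = "character"),
  validity = function(object) {
    need <- c("type", "elety", "resid", "chain", "resno", "insert",
              "x", "y", "z", "b", "elesy", "is_heavy")
    miss <- setdiff(need, names(object@atoms))
    if (length(miss) > 0)
      return(paste("atoms lacks columns:", paste(miss, collapse = ", ")))
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (nrow(xyz) > 0 && !all(is.finite(xyz)))
      return("non-finite atom coordinates")
    TRUE
  })

#' Contact-definition parameters
#'
#' Two residues are in contact when they form at least `min_atom_pairs`
#' atom--atom pairs within `atom_dist_cutoff` angstroms (inclusive) and are
#' separated by at least `min_seq_sep` positions along the chain.
#'
#' @slot atom_dist_cutoff numeric, pairwise atom distance cutoff in angstroms.
#' @slot min_atom_pairs integer, minimum number of qualifying atom pairs.
#' @slot min_seq_sep integer, minimum sequence separation `j - i`.
#' @slot heavy_only logical, restrict to heavy (non-hydrogen) atoms.
#'
#' @seealso [contactParams()]
#' @export
setClass("ContactParams",
  representation(atom_dist_cutoff = "numeric", min_atom_pairs = "integer",
                 min_seq_sep = "integer", heavy_only = "logical"),
  validity = function(object) {
    if (length(object@atom_dist_cutoff) != 1 || object@atom_dist_cutoff <= 0)
      return("atom_dist_cutoff must be a single positive number")
    if (object@min_atom_pairs < 1L) return("min_atom_pairs must be >= 1")
    if (object@min_seq_sep < 1L) return("min_seq_sep must be >= 1")
    TRUE
  })

#' Residue--residue contact map
#'
#' Contacts stored once each with `i < j`; `i`, `j` are sequence positions
#' (author residue numbers) and the interval of a contact is the span
#' `[i, j]` along the chain — the substrate of circuit-topology analysis.
#'
#' @slot contacts data.frame with columns `i`, `j`, `n_atom_pairs`.
#' @slot params the [ContactParams-class] used (or a placeholder when the
#'   map was constructed directly from intervals).
#'
#' @seealso [computeContacts()], [localTopology()], [contactCount()]
#' @export
setClass("ContactMap",
  representation(contacts = "data.frame", params = "ContactParams"),
  validity = function(object) {
    ct <- object@contacts
    if (!all(c("i", "j", "n_atom_pairs") %in% names(ct)))
      return("contacts needs columns i, j, n_atom_pairs")
    if (nrow(ct) > 0) {
      if (any(ct$i >= ct$j)) return("contacts must have i < j")
      if (anyDuplicated(ct[, c("i", "j")]) > 0)
        return("duplicate (i, j) contact")
    }
    TRUE
  })

#' Decision-tree split thresholds
#'
#' Thresholds of the rule cascade for chaperone responsiveness. The cascade
#' is: destabilization `ddg >= ddg_high` predicts non-responsive; ligand
#' contact predicts non-responsive; fewer than `contacts_small` contacts
#' predicts responsive; `ddg <= ddg_low` (strong stabilization) predicts
#' non-responsive; `ddg < ddg_mid` predicts responsive; otherwise the
#' inverse-parallel count decides, with `p_inv >= pinv_high` predicting
#' non-responsive.
#'
#' @slot ddg_high,ddg_mid,ddg_low numeric, kcal/mol.
#' @slot contacts_small integer; strict less-than comparison.
#' @slot pinv_high integer; greater-or-equal comparison.
#'
#' @seealso [treeThresholds()], [predictTree()]
#' @export
setClass("TreeThresholds",
  representation(ddg_high = "numeric", ddg_mid = "numeric",
                 ddg_low = "numeric", contacts_small = "integer",
                 pinv_high = "integer"),
  validity = function(object) {
    if (!(object@ddg_low < object@ddg_mid && object@ddg_mid < object@ddg_high))
      return("need ddg_low < ddg_mid < ddg_high")
    if (object@contacts_small < 1L) return("contacts_small must be >= 1")
    if (object@pinv_high < 1L) return("pinv_high must be >= 1")
    TRUE
  })

#' Rate constants of the ER folding/export scheme
#'
#' Unfolded protein U is supplied at rate `production`, degraded at `k_p`,
#' folds to F at `k_f`; F unfolds at `k_u`, binds chaperone at `kon_L`
#' (binding rate times ligand concentration, one effective parameter), or is
#' exported at `k_out`; the bound state F_B dissociates at `k_off` or is
#' exported at `k_out`.
#'
#' @slot production,k_p,k_f,k_u,kon_L,k_off,k_out numeric rates, all >= 0.
#'
#' @seealso [kineticParams()], [steadyState()], [rescueCurve()]
#' @export
setClass("KineticParams",
  representation(production = "numeric", k_p = "numeric", k_f = "numeric",
                 k_u = "numeric", kon_L = "numeric", k_off = "numeric",
                 k_out = "numeric"),
  validity = function(object) {
    v <- c(object@production, object@k_p, object@k_f, object@k_u,
           object@kon_L, object@k_off, object@k_out)
    if (length(v) != 7 || any(!is.finite(v))) return("all rates must be finite")
    if (any(v < 0)) return("all rates must be >= 0")
    if (object@k_p + object@k_f <= 0) return("need k_p + k_f > 0")
    TRUE
  })
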