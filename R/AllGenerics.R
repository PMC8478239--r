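#' @rdname computeContacts
#' @export
setGeneric("computeContacts", function(structure, params = contactParams())
  standardGeneric("computeContacts"))

#' @rdname localTopology
#' @export
setGeneric("localTopology", function(cmap, residue, count_pairs = FALSE)
  standardGeneric("localTopology"))

#' @rdname contactCount
#' @export
setGeneric("contactCount", function(cmap, residue)
  standardGeneric("contactCount"))

#' Accessor for the contact table of a ContactMap
#'
#' @param cmap a [ContactMap-class].
#' @return data.frame with columns `i`, `j`, `n_atom_pairs`, one row per
#'   contact, `i < j`.
#' @export
setGeneric("contactTable", function(cmap) standardGeneric("contactTable"))

#' @rdname contactTable
#' @export
setMethod("contactTable", "ContactMap", function(cmap) cmap@contacts)

#' Accessor for the atom table of a ProteinStructure
#'
#' @param x a [ProteinStructure-class].
#' @return data.frame of atoms (see the class documentation for columns).
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  pol <- a[a$type == "ATOM", ]
  het <- a[a$type == "HETATM", ]
  cat("ProteinStructure:", nrow(a), "atoms;",
      length(unique(paste(pol$chain, pol$resno, pol$insert))),
      "polymer residues in chain(s)",
      paste(sort(unique(pol$chain)), collapse = ","), "\n")
  if (nrow(het) > 0)
    cat("  het groups:",
        paste(sort(unique(het$resid)), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "ContactParams", function(object) {
  cat(sprintf(
    "ContactParams: cutoff %.2f A, >= %d atom pairs, seq sep >= %d, %s atoms\n",
    object@atom_dist_cutoff, object@min_atom_pairs, object@min_seq_sep,
    if (object@heavy_only) "heavy" else "all"))
  invisible(object)
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@contacts), "contacts\n")
  show(object@params)
  invisible(object)
})

setMethod("show", "TreeThresholds", function(object) {
  cat(sprintf(paste0(
    "TreeThresholds: ddg >= %.2f -> no; ligand -> no; contacts < %d -> yes;\n",
    "  ddg <= %.2f -> no; ddg < %.2f -> yes; p_inv >= %d -> no, else yes\n"),
    object@ddg_high, object@contacts_small, object@ddg_low, object@ddg_mid,
    object@pinv_high))
  invisible(object)
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(paste0(
    "KineticParams: production %.3g, k_p %.3g, k_f %.3g, k_u %.3g,\n",
    "  kon_L %.3g, k_off %.3g, k_out %.3g\n"),
    object@production, object@k_p, object@k_f, object@k_u,
    object@kon_L, object@k_off, object@k_out))
  invisible(object)
})
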