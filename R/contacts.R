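#' Contact-definition parameter sets
#'
#' Two presets are provided, reflecting the two contact definitions in use
#' for this class of analysis: `"methods"` requires at least 5 atom--atom
#' pairs (heavy atoms) within 4.5 angstroms, `"results"` requires at least
#' 6 heavy-atom pairs within 8 angstroms. Both exclude backbone neighbours
#' via `min_seq_sep = 2`. Individual fields can be overridden.
#'
#' @param preset `"methods"` (default) or `"results"`.
#' @param atom_dist_cutoff,min_atom_pairs,min_seq_sep,heavy_only overrides.
#' @return a [ContactParams-class].
#' @examples
#' contactParams()
#' contactParams("results")
#' contactParams(min_seq_sep = 3)
#' @export
contactParams <- function(preset = c("methods", "results"),
                          atom_dist_cutoff = NULL, min_atom_pairs = NULL,
                          min_seq_sep = NULL, heavy_only = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    methods = list(cutoff = 4.5, pairs = 5L, sep = 2L, heavy = TRUE),
    results = list(cutoff = 8.0, pairs = 6L, sep = 2L, heavy = TRUE))
  new("ContactParams",
      atom_dist_cutoff = if (is.null(atom_dist_cutoff)) def$cutoff
                         else as.numeric(atom_dist_cutoff),
      min_atom_pairs = if (is.null(min_atom_pairs)) def$pairs
                       else as.integer(min_atom_pairs),
      min_seq_sep = if (is.null(min_seq_sep)) def$sep
                    else as.integer(min_seq_sep),
      heavy_only = if (is.null(heavy_only)) def$heavy else isTRUE(heavy_only))
}

#' Compute the residue--residue contact map of a structure
#'
#' A contact between residues `i < j` is recorded when the number of
#' qualifying atom--atom pairs within the distance cutoff (inclusive) is at
#' least `min_atom_pairs` and `j - i >= min_seq_sep`. Only polymer residues
#' participate; only a single chain is meaningful because contact intervals
#' are spans of one sequence.
#'
#' @param structure a [ProteinStructure-class] with a single polymer chain
#'   (restrict at read time otherwise).
#' @param params a [ContactParams-class]; see [contactParams()].
#' @return a [ContactMap-class].
#' @examples
#' syn <- makeStructure(n_residues = 12, geometry = "hairpin")
#' tf <- tempfile(fileext = ".pdb")
#' writeLines(syn$pdb_text, tf)
#' cm <- computeContacts(readPDB(tf))
#' contactTable(cm)
#' @rdname computeContacts
#' @aliases computeContacts
#' @export
setMethod("computeContacts", "ProteinStructure",
          function(structure, params = contactParams()) {
  a <- polymerAtoms(structure)
  if (params@heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  chains <- unique(a$chain)
  if (length(chains) > 1)
    stop("structure has chains ", paste(chains, collapse = ", "),
         "; restrict to one chain with readPDB(path, chain = ...)")
  if (any(a$insert != ""))
    warning("insertion codes present; sequence positions use resno only")
  resnos <- sort(unique(a$resno))
  if (length(resnos) < 2) stop("need at least 2 polymer residues")

  xyz <- as.matrix(a[, c("x", "y", "z")])
  idx <- split(seq_len(nrow(a)), a$resno)
  idx <- idx[as.character(resnos)]
  cent <- t(vapply(idx, function(k) colMeans(xyz[k, , drop = FALSE]),
                   numeric(3)))
  rad <- vapply(seq_along(idx), function(r) {
    d2 <- rowSums((xyz[idx[[r]], , drop = FALSE] -
                   matrix(cent[r, ], length(idx[[r]]), 3, byrow = TRUE))^2)
    sqrt(max(d2))
  }, numeric(1))

  cd <- as.matrix(stats::dist(cent))
  out <- list()
  n <- length(resnos)
  cutoff <- params@atom_dist_cutoff
  for (r in seq_len(n - 1)) {
    for (s in (r + 1):n) {
      if (resnos[s] - resnos[r] < params@min_seq_sep) next
      if (cd[r, s] > cutoff + rad[r] + rad[s]) next  # centroid prefilter
      xi <- xyz[idx[[r]], , drop = FALSE]
      xj <- xyz[idx[[s]], , drop = FALSE]
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
      np <- sum(d2 <= cutoff^2 + 1e-9)
      if (np >= params@min_atom_pairs)
        out[[length(out) + 1]] <- c(resnos[r], resnos[s], np)
    }
  }
  ct <- if (length(out) == 0)
    data.frame(i = integer(), j = integer(), n_atom_pairs = integer())
  else {
    m <- do.call(rbind, out)
    data.frame(i = m[, 1], j = m[, 2], n_atom_pairs = m[, 3])
  }
  new("ContactMap", contacts = ct, params = params)
})

#' Build a ContactMap directly from contact intervals
#'
#' Constructs a map from an `(i, j)` table without reference to a structure;
#' used for synthetic maps and topology-only analyses.
#'
#' @param intervals data.frame (or 2/3-column matrix) with columns `i`, `j`
#'   and optionally `n_atom_pairs`.
#' @param params a [ContactParams-class] recorded with the map.
#' @return a [ContactMap-class].
#' @export
contactMapFromIntervals <- function(intervals, params = contactParams()) {
  intervals <- as.data.frame(intervals)
  if (ncol(intervals) >= 2 && !all(c("i", "j") %in% names(intervals)))
    names(intervals)[1:2] <- c("i", "j")
  if (nrow(intervals) == 0) {
    ct <- data.frame(i = integer(), j = integer(), n_atom_pairs = integer())
    return(new("ContactMap", contacts = ct, params = params))
  }
  ij <- t(apply(intervals[, c("i", "j")], 1, sort))
  ct <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                   n_atom_pairs = if ("n_atom_pairs" %in% names(intervals))
                     as.integer(intervals$n_atom_pairs)
                   else rep(NA_integer_, nrow(intervals)))
  ct <- ct[order(ct$i, ct$j), , drop = FALSE]
  rownames(ct) <- NULL
  new("ContactMap", contacts = ct, params = params)
}

#' Write / read contact maps as TSV
#'
#' @param cmap a [ContactMap-class].
#' @param path output (or input) TSV path with columns `i`, `j`,
#'   `n_atom_pairs`.
#' @return `readContactMap` returns a [ContactMap-class].
#' @export
writeContactMap <- function(cmap, path) {
  utils::write.table(contactTable(cmap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeContactMap
#' @export
readContactMap <- function(path) {
  contactMapFromIntervals(utils::read.delim(path))
}
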