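RELATION_LEVELS <- c("S", "P", "Pinv", "X", "concerted")

#' Circuit-topology relation between two contacts
#'
#' Classifies the relation of contact `a` with respect to contact `b` from
#' their sequence intervals: `"P"` (parallel) when a's interval lies strictly
#' inside b's, `"Pinv"` (inverse parallel) when a strictly contains b —
#' i.e. a is the outer contact of a nested pair — `"S"` (series) when the
#' intervals are disjoint, `"X"` (cross) when they partially overlap, and
#' `"concerted"` when the two contacts share an endpoint. By construction
#' `contactRelation(a, b) == "P"` iff `contactRelation(b, a) == "Pinv"`,
#' while `"S"`, `"X"` and `"concerted"` are symmetric.
#'
#' @param a,b length-2 integer vectors `(i, j)` with `i < j`.
#' @return one of `"S"`, `"P"`, `"Pinv"`, `"X"`, `"concerted"`.
#' @examples
#' contactRelation(c(3, 6), c(1, 10))  # "P": nested inside
#' contactRelation(c(1, 10), c(3, 6))  # "Pinv": the outer contact
#' contactRelation(c(1, 3), c(5, 8))   # "S"
#' contactRelation(c(1, 5), c(3, 8))   # "X"
#' @export
contactRelation <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != 2 || length(b) != 2 || a[1] >= a[2] || b[1] >= b[2])
    stop("contacts must be (i, j) pairs with i < j")
  if (a[1] == b[1] && a[2] == b[2])
    stop("relation of a contact with itself is undefined")
  if (a[1] %in% b || a[2] %in% b) return("concerted")
  if (a[1] > b[1] && a[2] < b[2]) return("P")
  if (a[1] < b[1] && a[2] > b[2]) return("Pinv")
  if (a[2] < b[1] || b[2] < a[1]) return("S")
  "X"
}

#' Local circuit topology of a residue
#'
#' Counts, for each relation type, the contacts of the map standing in that
#' relation to at least one contact formed by the given residue. Direction
#' matters for nesting: a residue's inverse-parallel (`Pinv`) count is the
#' number of *outer* contacts containing one of its own contacts, so
#' residues sitting on inner (presumed early-folding) contacts score high.
#' The residue's own contacts are excluded from its counts, shared-endpoint
#' (concerted) pairs are excluded from the four basic counts, and each
#' qualifying contact is counted once per relation type; set
#' `count_pairs = TRUE` to count contact--contact pairs instead.
#'
#' @param cmap a [ContactMap-class].
#' @param residue sequence position (author residue number).
#' @param count_pairs logical; count (contact, own-contact) pairs rather than
#'   distinct contacts.
#' @return named integer vector with elements `series`, `parallel`,
#'   `inverse_parallel`, `cross`; all zero when the residue forms no contact.
#' @examples
#' cm <- contactMapFromIntervals(data.frame(i = c(1, 3), j = c(10, 6)))
#' localTopology(cm, 3)   # inverse_parallel = 1: (1,10) contains (3,6)
#' localTopology(cm, 1)   # parallel = 1: (3,6) nested inside (1,10)
#' @rdname localTopology
#' @aliases localTopology
#' @export
setMethod("localTopology", "ContactMap",
          function(cmap, residue, count_pairs = FALSE) {
  ct <- cmap@contacts
  zero <- c(series = 0L, parallel = 0L, inverse_parallel = 0L, cross = 0L)
  own <- ct$i == residue | ct$j == residue
  if (!any(own)) return(zero)
  others <- which(!own)
  if (length(others) == 0) return(zero)
  counts <- zero
  key <- c(S = "series", P = "parallel", Pinv = "inverse_parallel",
           X = "cross")
  for (x in others) {
    seen <- character(0)
    for (c0 in which(own)) {
      rel <- contactRelation(c(ct$i[x], ct$j[x]), c(ct$i[c0], ct$j[c0]))
      if (rel == "concerted") next
      if (count_pairs || !(rel %in% seen)) {
        counts[key[[rel]]] <- counts[key[[rel]]] + 1L
        seen <- c(seen, rel)
      }
    }
  }
  counts
})

#' Number of residues in contact with a residue
#'
#' @param cmap a [ContactMap-class].
#' @param residue sequence position.
#' @return integer count of distinct contact partners (0 when isolated).
#' @rdname contactCount
#' @aliases contactCount
#' @export
setMethod("contactCount", "ContactMap", function(cmap, residue) {
  ct <- cmap@contacts
  partners <- c(ct$j[ct$i == residue], ct$i[ct$j == residue])
  length(unique(partners))
})

#' Exhaustive pairwise relation table
#'
#' Labels every ordered pair of contacts by direct interval comparison,
#' using interval set membership rather than endpoint inequalities — an
#' independent code path from [contactRelation()], intended as a
#' brute-force oracle.
#'
#' @param cmap a [ContactMap-class].
#' @param limit refuse maps with more contacts than this.
#' @return data.frame with columns `a_i`, `a_j`, `b_i`, `b_j`, `relation`,
#'   one row per ordered pair of distinct contacts.
#' @export
bruteForceRelations <- function(cmap, limit = 100L) {
  ct <- contactTable(cmap)
  n <- nrow(ct)
  if (n > limit) stop("contact map has ", n, " contacts; limit is ", limit)
  empty <- data.frame(a_i = integer(), a_j = integer(), b_i = integer(),
                      b_j = integer(), relation = character())
  if (n < 2) return(empty)
  rows <- list()
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (p == q) next
    ia <- ct$i[p]:ct$j[p]
    ib <- ct$i[q]:ct$j[q]
    shared_end <- any(c(ct$i[p], ct$j[p]) %in% c(ct$i[q], ct$j[q]))
    common <- intersect(ia, ib)
    rel <- if (shared_end) "concerted"
      else if (length(common) == 0) "S"
      else if (setequal(common, ia) && !setequal(common, ib)) "P"
      else if (setequal(common, ib) && !setequal(common, ia)) "Pinv"
      else "X"
    rows[[length(rows) + 1]] <-
      data.frame(a_i = ct$i[p], a_j = ct$j[p], b_i = ct$i[q], b_j = ct$j[q],
                 relation = rel)
  }
  do.call(rbind, rows)
}

#' Write a pairwise relation table as TSV
#'
#' @param relations data.frame from [bruteForceRelations()].
#' @param path output path.
#' @export
writeRelationTable <- function(relations, path) {
  utils::write.table(relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
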