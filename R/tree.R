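#' Decision-tree thresholds (published defaults)
#'
#' The split values of the responsiveness rule cascade. `ddg_high = 1.7`,
#' `ddg_mid = 0.94` and `ddg_low = -1.4` kcal/mol are the published splits.
#' The contact-count and inverse-parallel splits are not printed at full
#' precision in the source tree figure; `contacts_small = 4` is the midpoint
#' of the interval (3, 5] consistent with the worked Gaucher examples, and
#' `pinv_high = 100` is an arbitrary choice within the admissible range
#' (any value in \\[1, 219\\] reproduces those examples) — both are
#' configurable and should be treated as approximate.
#'
#' @param ddg_high,ddg_mid,ddg_low numeric, kcal/mol.
#' @param contacts_small integer (strict less-than split).
#' @param pinv_high integer (greater-or-equal split).
#' @return a [TreeThresholds-class].
#' @export
treeThresholds <- function(ddg_high = 1.7, ddg_mid = 0.94, ddg_low = -1.4,
                           contacts_small = 4L, pinv_high = 100L) {
  new("TreeThresholds", ddg_high = ddg_high, ddg_mid = ddg_mid,
      ddg_low = ddg_low, contacts_small = as.integer(contacts_small),
      pinv_high = as.integer(pinv_high))
}

#' Leaf probabilities of the responsive class
#'
#' Per-leaf probability `p1` of the responsive class. The values for
#' `small_contacts` (0.60), `root_destab` (0.28) and `pinv_high` (0.34) are
#' the published leaf outputs; the remaining four leaves are not printed in
#' the source and default to the class-typical values 0.28 (non-responsive
#' leaves `ligand`, `over_stabilized`) and 0.60 (responsive leaves
#' `mid_ddg`, `pinv_low`) — override them if better estimates are
#' available.
#'
#' @param ... named overrides for individual leaves.
#' @return named numeric vector over the 7 leaf ids.
#' @export
defaultLeafProbs <- function(...) {
  p <- c(root_destab = 0.28, ligand = 0.28, small_contacts = 0.60,
         over_stabilized = 0.28, mid_ddg = 0.60, pinv_high = 0.34,
         pinv_low = 0.60)
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) > 0) stop("unknown leaf id(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- as.numeric(unlist(over))
  }
  if (any(p < 0 | p > 1)) stop("leaf probabilities must lie in [0, 1]")
  p
}

#' Predict chaperone responsiveness of one variant
#'
#' Applies the rule cascade: (1) `ddg >= ddg_high` -> non-responsive
#' (leaf `root_destab`); (2) ligand contact -> non-responsive (`ligand`);
#' (3) `n_contacts < contacts_small` -> responsive (`small_contacts`);
#' (4) `ddg <= ddg_low` -> non-responsive (`over_stabilized`);
#' (5) `ddg < ddg_mid` -> responsive (`mid_ddg`);
#' (6) `p_inv >= pinv_high` -> non-responsive (`pinv_high`), else
#' responsive (`pinv_low`). Every comparison is recorded in the trace.
#'
#' @param features list or one-row data.frame with `ddg`, `binds_ligand`,
#'   `n_contacts`, `p_inv`.
#' @param thresholds a [TreeThresholds-class].
#' @param leaves named numeric from [defaultLeafProbs()].
#' @return list with elements `label` (logical, responsive), `p1`
#'   (leaf probability of the responsive class), `leaf` (leaf id) and
#'   `trace` (character vector of node decisions).
#' @examples
#' predictTree(list(ddg = 0.28, binds_ligand = FALSE,
#'                  n_contacts = 3, p_inv = 183))
#' @export
predictTree <- function(features, thresholds = treeThresholds(),
                        leaves = defaultLeafProbs()) {
  f <- as.list(features)
  need <- c("ddg", "binds_ligand", "n_contacts", "p_inv")
  for (nm in need)
    if (is.null(f[[nm]]) || is.na(f[[nm]]))
      stop("missing required feature: ", nm)
  th <- thresholds
  trace <- character(0)
  note <- function(txt) trace <<- c(trace, txt)

  leaf <- NULL
  if (f$ddg >= th@ddg_high) {
    note(sprintf("ddg %.3g >= %.3g : TRUE", f$ddg, th@ddg_high))
    leaf <- "root_destab"
  } else {
    note(sprintf("ddg %.3g >= %.3g : FALSE", f$ddg, th@ddg_high))
    if (isTRUE(as.logical(f$binds_ligand))) {
      note("binds_ligand : TRUE")
      leaf <- "ligand"
    } else {
      note("binds_ligand : FALSE")
      if (f$n_contacts < th@contacts_small) {
        note(sprintf("n_contacts %d < %d : TRUE", f$n_contacts,
                     th@contacts_small))
        leaf <- "small_contacts"
      } else {
        note(sprintf("n_contacts %d < %d : FALSE", f$n_contacts,
                     th@contacts_small))
        if (f$ddg <= th@ddg_low) {
          note(sprintf("ddg %.3g <= %.3g : TRUE", f$ddg, th@ddg_low))
          leaf <- "over_stabilized"
        } else if (f$ddg < th@ddg_mid) {
          note(sprintf("ddg %.3g <= %.3g : FALSE; ddg < %.3g : TRUE",
                       f$ddg, th@ddg_low, th@ddg_mid))
          leaf <- "mid_ddg"
        } else if (f$p_inv >= th@pinv_high) {
          note(sprintf("ddg %.3g in [%.3g, %.3g); p_inv %d >= %d : TRUE",
                       f$ddg, th@ddg_mid, th@ddg_high, f$p_inv, th@pinv_high))
          leaf <- "pinv_high"
        } else {
          note(sprintf("ddg %.3g in [%.3g, %.3g); p_inv %d >= %d : FALSE",
                       f$ddg, th@ddg_mid, th@ddg_high, f$p_inv, th@pinv_high))
          leaf <- "pinv_low"
        }
      }
    }
  }
  p1 <- unname(leaves[[leaf]])
  list(label = p1 >= 0.5, p1 = p1, leaf = leaf, trace = trace)
}

#' Predict responsiveness for a table of variants
#'
#' Row-wise [predictTree()], order preserved; per-row errors are collected
#' and reported together.
#'
#' @param features data.frame with columns `ddg`, `binds_ligand`,
#'   `n_contacts`, `p_inv` and optionally `variant`.
#' @inheritParams predictTree
#' @return data.frame with columns `variant` (when present), `responsive`
#'   (logical), `p1`, `leaf`, `trace` (single string, steps joined by
#'   `" | "`).
#' @export
predictTreeBatch <- function(features, thresholds = treeThresholds(),
                             leaves = defaultLeafProbs()) {
  f <- as.data.frame(features)
  n <- nrow(f)
  out <- data.frame(responsive = logical(n), p1 = numeric(n),
                    leaf = character(n), trace = character(n))
  if ("variant" %in% names(f)) out <- cbind(variant = f$variant, out)
  errs <- character(0)
  for (k in seq_len(n)) {
    res <- tryCatch(predictTree(f[k, , drop = FALSE], thresholds, leaves),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("row %d: %s", k, conditionMessage(res)))
      next
    }
    out$responsive[k] <- res$label
    out$p1[k] <- res$p1
    out$leaf[k] <- res$leaf
    out$trace[k] <- paste(res$trace, collapse = " | ")
  }
  if (length(errs) > 0)
    stop("prediction failed for ", length(errs), " row(s):\n",
         paste(errs, collapse = "\n"))
  out
}

#' Compare predictions with observed labels
#'
#' @param predicted logical (or yes/no) predicted responsiveness.
#' @param observed logical (or yes/no) assay labels.
#' @return list with `n`, `n_correct`, `accuracy`, the confusion counts
#'   (`tp`, `fp`, `tn`, `fn`; responsive is the positive class) and `mcc`
#'   (`NA` when the observed labels contain a single class).
#' @export
evaluatePredictions <- function(predicted, observed) {
  p <- normalizeYesNo(predicted)
  o <- normalizeYesNo(observed)
  if (length(p) != length(o))
    stop("predicted and observed differ in length (", length(p), " vs ",
         length(o), ")")
  if (any(is.na(p)) || any(is.na(o))) stop("labels contain NA")
  tp <- sum(p & o); fp <- sum(p & !o); tn <- sum(!p & !o); fn <- sum(!p & o)
  list(n = length(p), n_correct = tp + tn,
       accuracy = (tp + tn) / length(p),
       tp = tp, fp = fp, tn = tn, fn = fn,
       mcc = if (length(unique(o)) < 2) NA_real_ else mcc(tp, fp, tn, fn))
}
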