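#' Matthews correlation coefficient
#'
#' `(tp * tn - fp * fn) / sqrt((tp + fp)(tp + fn)(tn + fp)(tn + fn))`,
#' computed in double precision. When any margin is zero the denominator
#' vanishes and 0 is returned (the common convention for the degenerate
#' case).
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return numeric in \\[-1, 1\\].
#' @examples
#' mcc(5, 0, 5, 0)  # 1
#' mcc(0, 5, 0, 5)  # -1
#' @export
mcc <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("confusion counts must be non-negative finite numbers")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Rank-based area under the ROC curve
#'
#' Mann--Whitney AUC with midrank tie handling: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, ties
#' counting one half.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels logical (or yes/no) class labels; both classes required.
#' @return numeric in \\[0, 1\\].
#' @examples
#' aucScore(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
aucScore <- function(scores, labels) {
  lab <- normalizeYesNo(labels)
  if (length(scores) != length(lab)) stop("scores and labels differ in length")
  if (any(is.na(scores)) || any(is.na(lab))) stop("NA in scores or labels")
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both classes; got ", n1, " positives and ", n0,
         " negatives")
  r <- rank(scores)  # midranks
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion table from label vectors
#'
#' @param predicted,observed logical (or yes/no) labels.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusionTable <- function(predicted, observed) {
  p <- normalizeYesNo(predicted)
  o <- normalizeYesNo(observed)
  if (length(p) != length(o)) stop("length mismatch")
  c(tp = sum(p & o), fp = sum(p & !o), tn = sum(!p & !o), fn = sum(!p & o))
}
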