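#' @import methods
#' @importFrom stats median sd quantile rnorm runif rbinom approx predict
#' @importFrom utils read.delim write.table head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib guidescreen, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FNV-1a hash of a character vector
#'
#' Deterministic 32-bit FNV-1a hash, used to fingerprint feature rosters so
#' a fitted model can refuse feature matrices with a different layout.
#'
#' @param x character vector (collapsed with "\\x1f" separators before hashing)
#' @return hex string of the 32-bit hash
#' @export
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits (h is kept as a double)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so intermediate products stay inside double precision
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo16 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo16) / 65536), as.integer(lo16))
}

#' Reverse complement of a DNA string
#' @param x character scalar or vector of DNA sequences
#' @return reverse complement(s), uppercase
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) if (!isTRUE(cond)) stopf(fmt, ...)

#' Area under the ROC curve by trapezoid over the full ranking
#'
#' Computes the ROC curve from a numeric ranking (higher score = predicted
#' positive) and integrates it by trapezoid. Ties are handled by grouping
#' tied scores into single steps (diagonal segments).
#'
#' @param scores numeric ranking
#' @param labels logical (or 0/1) true class
#' @return list with `auc`, and vectors `fpr`, `tpr`
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  assert_that(length(scores) == length(labels), "scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stopf("ROC undefined: test set contains a single class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # group ties
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- cumsum(tapply(l, grp, sum))
  fp <- cumsum(tapply(!l, grp, sum))
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = unname(auc), fpr = unname(fpr), tpr = unname(tpr))
}

#' Precision-recall curve and recall at a precision target
#'
#' Ranks items by score (higher = called first) and computes precision and
#' recall at every threshold. `recall_at_precision` uses the interpolated
#' (running-maximum from the high-precision end) curve, the standard
#' convention for "recall at X% precision" readouts.
#'
#' @param scores numeric ranking (higher ranked first)
#' @param labels logical true positives
#' @return list with `precision`, `recall`, `auprc` and function-like access
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  np <- sum(labels)
  if (np == 0L || sum(!labels) == 0L) stopf("PR undefined: need both classes")
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]; s <- scores[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- cumsum(tapply(l, grp, sum))
  n_called <- cumsum(tapply(rep(1L, length(l)), grp, sum))
  precision <- tp / n_called
  recall <- tp / np
  # interpolated precision: best precision achievable at >= this recall
  interp <- rev(cummax(rev(precision)))
  # step-wise AUPRC on the interpolated curve
  auprc <- sum(diff(c(0, recall)) * interp)
  list(precision = unname(precision), recall = unname(recall),
       interpolated_precision = unname(interp), auprc = unname(auprc))
}

#' @rdname pr_curve
#' @param target precision level, e.g. 0.95
#' @export
recall_at_precision <- function(scores, labels, target = 0.95) {
  pr <- pr_curve(scores, labels)
  ok <- pr$interpolated_precision >= target
  if (!any(ok)) return(0)
  max(pr$recall[ok])
}
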