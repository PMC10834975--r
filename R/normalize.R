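#' TPM normalization for equal-length features
#'
#' Mature miRNAs are treated as having equal effective length, so TPM
#' reduces to the per-million share of each sample's counts: every column
#' of the result sums to 1e6.
#'
#' @param x \code{ExpressionMatrix} on the \code{raw_count} scale.
#' @return \code{ExpressionMatrix} on the \code{tpm} scale.
#' @export
compute_tpm <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "raw_count") stop("compute_tpm expects raw counts, got scale ", x$scale)
  totals <- colSums(x$values)
  if (any(totals <= 0)) {
    stop("all-zero count column for sample(s): ",
         paste(colnames(x$values)[totals <= 0], collapse = ", "))
  }
  out <- x
  out$values <- sweep(x$values, 2, totals, "/") * 1e6
  out$scale <- "tpm"
  out
}

#' Quantile normalization
#'
#' Columns are forced onto a common distribution: the reference is the mean
#' of the column-wise sorted values, and each value is replaced by the
#' reference quantile at its within-column rank. Tied values receive the
#' mean of the reference quantiles they jointly occupy, which makes the
#' transform deterministic and idempotent.
#'
#' @param values Numeric matrix.
#' @return Matrix of the same shape; column-wise sorted values identical.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) == 1) return(values)
  ref <- rowMeans(apply(values, 2, sort))
  out <- values
  for (j in seq_len(ncol(values))) {
    o <- order(values[, j])
    sorted <- values[o, j]
    grp <- cumsum(c(TRUE, diff(sorted) != 0))
    out[o, j] <- ave(ref, grp)
  }
  out
}

#' log2 then quantile normalization of TPM
#'
#' @param x \code{ExpressionMatrix} on the \code{tpm} scale.
#' @param pseudocount Positive offset added before the log. Default 1.
#' @return \code{ExpressionMatrix} on the \code{qnorm_log2tpm} scale.
#' @export
log2_quantile_normalize <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"), pseudocount > 0)
  if (x$scale != "tpm") {
    stop("log2_quantile_normalize expects TPM input, got scale ", x$scale)
  }
  out <- x
  out$values <- quantile_normalize(log2(x$values + pseudocount))
  out$scale <- "qnorm_log2tpm"
  out
}
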