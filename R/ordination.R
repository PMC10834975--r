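#' Ordination-based quality control
#'
#' Principal component analysis on centered features, the sample-sample
#' Pearson correlation matrix, and average-linkage hierarchical clustering
#' on correlation distance (1 - r). Samples with zero variance have no
#' defined correlation; they are flagged and excluded from the correlation
#' matrix and the dendrogram, but kept in the PCA.
#'
#' @param x \code{ExpressionMatrix}, typically on the \code{qnorm_log2tpm}
#'   scale.
#' @return List with \code{pca} (data frame of sample coordinates plus
#'   metadata), \code{var_explained}, \code{pearson} (correlation matrix),
#'   \code{hclust}, and \code{excluded} (constant samples).
#' @export
ordination_qc <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2) stop("ordination_qc needs at least two samples")
  constant <- apply(x$values, 2, function(v) var(v) == 0)
  if (any(constant)) {
    warning("constant sample(s) excluded from correlation/clustering: ",
            paste(colnames(x$values)[constant], collapse = ", "))
  }
  pc <- prcomp(t(x$values), center = TRUE, scale. = FALSE)
  coords <- as.data.frame(pc$x)
  coords <- cbind(x$samples[, c("sample_id", "tissue", "age", "replicate")], coords)
  rownames(coords) <- NULL
  keep <- !constant
  pearson <- cor(x$values[, keep, drop = FALSE])
  hc <- if (sum(keep) >= 2) {
    hclust(stats::as.dist(1 - pearson), method = "average")
  } else NULL
  list(pca = coords,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       pearson = pearson,
       hclust = hc,
       excluded = colnames(x$values)[constant])
}
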