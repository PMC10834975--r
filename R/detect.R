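#' Detection calling from read counts
#'
#' A miRNA is expressed in a sample when its count strictly exceeds the
#' threshold (default: more than five reads). Per-(tissue, age) group calls
#' summarize the replicates by the chosen rule: "mean" (group mean count >
#' threshold, the default), "any" (expressed in at least one replicate) or
#' "all".
#'
#' @param x \code{ExpressionMatrix} of counts (reads).
#' @param threshold Strict lower bound. Default 5.
#' @param group_rule "mean", "any" or "all".
#' @return A \code{DetectionTable}: \code{per_replicate} logical matrix
#'   (feature x sample) and \code{per_group} logical array
#'   (feature x tissue x age; NA for groups with no samples).
#' @export
call_detection_reads <- function(x, threshold = 5,
                                 group_rule = c("mean", "any", "all")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  group_rule <- match.arg(group_rule)
  per_replicate <- x$values > threshold
  tissues <- unique(x$samples$tissue)
  ages <- unique(x$samples$age)
  per_group <- array(NA, dim = c(nrow(x$values), length(tissues), length(ages)),
                     dimnames = list(rownames(x$values), tissues, ages))
  for (t in tissues) {
    for (a in ages) {
      idx <- which(x$samples$tissue == t & x$samples$age == a)
      if (length(idx) == 0) next
      sub <- x$values[, idx, drop = FALSE]
      per_group[, t, a] <- switch(group_rule,
        mean = rowMeans(sub) > threshold,
        any  = rowSums(sub > threshold) > 0,
        all  = rowSums(sub > threshold) == length(idx)
      )
    }
  }
  empty <- sum(is.na(per_group[1, , ]))
  if (empty > 0) warning(empty, " (tissue, age) group(s) have no samples; calls set to NA")
  structure(list(per_replicate = per_replicate, per_group = per_group,
                 samples = x$samples, threshold = threshold, rule = group_rule),
            class = "DetectionTable")
}

#' Detection calling from UMI counts
#'
#' A miRNA is detected in a compartment-age group when the sum of its UMIs
#' across the group's replicates reaches the threshold (inclusive; default
#' a minimum UMI sum of 10 in 3 replicates).
#'
#' @param x \code{ExpressionMatrix} of UMI counts (\code{count_unit} "UMI").
#' @param threshold Inclusive lower bound on the group UMI sum. Default 10.
#' @return A \code{DetectionTable}; \code{per_replicate} records nonzero
#'   UMIs per sample, \code{per_group} carries the group-sum call.
#' @export
call_detection_umi <- function(x, threshold = 10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!all(x$samples$count_unit == "UMI")) {
    stop("call_detection_umi expects UMI counts (count_unit = 'UMI')")
  }
  tissues <- unique(x$samples$tissue)
  ages <- unique(x$samples$age)
  per_group <- array(NA, dim = c(nrow(x$values), length(tissues), length(ages)),
                     dimnames = list(rownames(x$values), tissues, ages))
  for (t in tissues) {
    for (a in ages) {
      idx <- which(x$samples$tissue == t & x$samples$age == a)
      if (length(idx) == 0) next
      if (length(idx) != 3) {
        warning("group (", t, ", ", a, ") has ", length(idx),
                " replicates; UMI-sum rule applied to those available")
      }
      per_group[, t, a] <- rowSums(x$values[, idx, drop = FALSE]) >= threshold
    }
  }
  structure(list(per_replicate = x$values > 0, per_group = per_group,
                 samples = x$samples, threshold = threshold, rule = "umi_sum"),
            class = "DetectionTable")
}

#' @export
print.DetectionTable <- function(x, ...) {
  cat(sprintf("DetectionTable (%s, threshold %s): %d features, %d samples\n",
              x$rule, format(x$threshold), nrow(x$per_replicate), ncol(x$per_replicate)))
  cat("  detected in >=1 group:", sum(apply(x$per_group, 1, any, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Detection table as a tidy data frame
#'
#' @param det A \code{DetectionTable}.
#' @return Long data frame: feature_id, tissue, age, expressed.
#' @export
detection_long <- function(det) {
  d <- dimnames(det$per_group)
  long <- expand.grid(feature_id = d[[1]], tissue = d[[2]], age = d[[3]],
                      stringsAsFactors = FALSE)
  long$expressed <- as.vector(det$per_group)
  long[!is.na(long$expressed), , drop = FALSE]
}
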