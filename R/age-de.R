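boxcox_loglik <- function(x, lambda) {
  z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  n <- length(x)
  v <- sum((z - mean(z))^2) / n
  if (!is.finite(v) || v <= 0) return(-Inf)  # degenerate: collapsed variance
  -n / 2 * log(v) + (lambda - 1) * sum(log(x))
}

#' Box-Cox transform with maximum-likelihood lambda
#'
#' \eqn{y = (x^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0}, \eqn{\log x}
#' for \eqn{\lambda = 0}. When no lambda is supplied it is chosen by
#' profile maximum likelihood on the pooled values. A constant vector
#' admits any lambda; the documented tie-break returns \eqn{\lambda = 1}
#' (the shape-preserving shift \eqn{x - 1}).
#'
#' @param x Positive numeric vector.
#' @param lambda Optional fixed lambda.
#' @param interval Search interval for the MLE. Default c(-2, 2).
#' @return List with \code{transformed} and \code{lambda}.
#' @export
boxcox_transform <- function(x, lambda = NULL, interval = c(-2, 2)) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("boxcox_transform requires strictly positive finite values")
  }
  if (is.null(lambda)) {
    if (length(unique(x)) == 1) {
      lambda <- 1
    } else {
      lambda <- optimize(function(l) boxcox_loglik(x, l),
                         interval = interval, maximum = TRUE)$maximum
    }
  }
  transformed <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(transformed = transformed, lambda = lambda)
}

#' Two-sided pooled-variance t-test between age groups
#'
#' Student's two-sample t-test (pooled variance) on, by convention,
#' Box-Cox-transformed values; \code{t} is signed as D8 minus D1. With zero
#' pooled variance the test is degenerate: equal means give p = 1, unequal
#' means give p = 0 with \code{degenerate = TRUE}.
#'
#' @param d1,d8 Numeric vectors (each length >= 2).
#' @return List with \code{t}, \code{p}, \code{df}, \code{degenerate}.
#' @export
ttest_age <- function(d1, d8) {
  if (length(d1) < 2 || length(d8) < 2) {
    stop("ttest_age needs at least two values per group")
  }
  n1 <- length(d1); n2 <- length(d8)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(d1) + (n2 - 1) * var(d8)) / df
  delta <- mean(d8) - mean(d1)
  if (sp2 <= 0) {
    if (delta == 0) return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    return(list(t = sign(delta) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df), df = df, degenerate = FALSE)
}

#' Call age-dependent differentially expressed miRNAs (Age-DEMIRs)
#'
#' Per tissue (or compartment), every miRNA expressed there at D1 or D8 is
#' tested for a D1-vs-D8 difference by a two-sided pooled-variance t-test
#' after a per-miRNA Box-Cox transform of the pooled values. In "tissue"
#' mode significance is p < p_threshold alone; in "compartment" mode
#' (worm/EV libraries) the fold change must additionally exceed
#' fc_threshold or fall below its reciprocal. Fold change is the ratio of
#' untransformed group means after adding the pseudocount, D8 over D1.
#'
#' @param x \code{ExpressionMatrix} on the \code{tpm} (or
#'   \code{relative_abundance}) scale.
#' @param detection \code{DetectionTable} aligned with \code{x}.
#' @param cfg \code{analysis_config}.
#' @param mode "tissue" (p-only criterion) or "compartment" (p and FC).
#' @return List with \code{results} (one row per tested miRNA x tissue:
#'   mean_d1, mean_d8, fold_change, lambda, t, p, fdr, significant,
#'   direction) and \code{demirs} (per-tissue up/down sets plus their
#'   union).
#' @export
call_age_demirs <- function(x, detection, cfg = analysis_config(),
                            mode = c("tissue", "compartment")) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(detection, "DetectionTable"))
  mode <- match.arg(mode)
  pc <- cfg$pseudocount
  tissues <- dimnames(detection$per_group)[[2]]
  ages <- dimnames(detection$per_group)[[3]]
  if (!all(c("D1", "D8") %in% ages)) stop("detection table must cover ages D1 and D8")
  rows <- list()
  for (t in tissues) {
    i1 <- which(x$samples$tissue == t & x$samples$age == "D1")
    i8 <- which(x$samples$tissue == t & x$samples$age == "D8")
    if (length(i1) < 2 || length(i8) < 2) {
      warning("tissue ", t, " lacks replicates in one age group; skipped")
      next
    }
    e1 <- detection$per_group[, t, "D1"]
    e8 <- detection$per_group[, t, "D8"]
    tested <- which((!is.na(e1) & e1) | (!is.na(e8) & e8))
    for (m in tested) {
      v1 <- x$values[m, i1] + pc
      v8 <- x$values[m, i8] + pc
      bc <- boxcox_transform(c(v1, v8))
      tt <- ttest_age(bc$transformed[seq_along(v1)],
                      bc$transformed[length(v1) + seq_along(v8)])
      fc <- mean(v8) / mean(v1)
      rows[[length(rows) + 1]] <- data.frame(
        mature_id = rownames(x$values)[m], tissue = t,
        mean_d1 = mean(x$values[m, i1]), mean_d8 = mean(x$values[m, i8]),
        fold_change = fc, lambda = bc$lambda, t = tt$t, p = tt$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(list(results = data.frame(), demirs = list(per_tissue = list(), union = character())))
  }
  res <- do.call(rbind, rows)
  res$fdr <- ave(res$p, res$tissue, FUN = function(p) p.adjust(p, "BH"))
  fc_ok <- if (mode == "compartment") {
    res$fold_change > cfg$fc_threshold | res$fold_change < 1 / cfg$fc_threshold
  } else TRUE
  res$significant <- res$p < cfg$p_threshold & fc_ok
  res$direction <- ifelse(!res$significant, "unchanged",
                          ifelse(res$fold_change > 1, "up", "down"))
  per_tissue <- lapply(split(res, res$tissue), function(d) {
    list(up = d$mature_id[d$direction == "up"],
         down = d$mature_id[d$direction == "down"])
  })
  union_set <- sort(unique(res$mature_id[res$significant]))
  list(results = res, demirs = list(per_tissue = per_tissue, union = union_set))
}

#' Two-proportion z-test on pooled UMI counts
#'
#' Count-based alternative to the Box-Cox t-test for UMI libraries: the
#' miRNA's pooled UMIs at each age are treated as successes out of the
#' library totals, and compared by the pooled two-proportion z statistic
#' z = (p1 - p2) / sqrt(p(1 - p)(1/N1 + 1/N2)) with pooled p.
#'
#' @param x1,x2 Pooled UMI counts of one miRNA in the two conditions.
#' @param n1,n2 Total UMI counts of the two conditions (n >= x >= 0).
#' @return List with \code{z} (condition 2 minus condition 1), \code{p}
#'   (two-sided normal).
#' @export
umi_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p2 - p1) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}
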