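#' Default tissue and compartment vocabulary
#'
#' The five profiled somatic tissues (neuron, intestine, body wall muscle,
#' hypodermis, coelomocyte) plus the whole-worm and extracellular-vesicle
#' compartments used by the UMI libraries.
#'
#' @return Character vector of tissue labels.
#' @export
worm_tissues <- function() c("Neu", "Int", "BWM", "Hyp", "Coel")

#' @rdname worm_tissues
#' @export
worm_compartments <- function() c("Worm", "EV")

#' @rdname worm_tissues
#' @export
worm_ages <- function() c("D1", "D8")

#' Analysis configuration
#'
#' Bundles every threshold used by the pipeline. Defaults are the study
#' cut-offs: a miRNA is expressed in a tissue when it exceeds 5 reads
#' (strict \code{>}), a UMI library calls a miRNA detected at a group UMI
#' sum of at least 10 over 3 replicates, age-dependent change requires
#' p < 0.05 (plus fold-change > 1.5 or < 1/1.5 in compartment mode), a
#' target needs Pearson correlation below -0.2, and secretion classes use
#' a 2-fold change of the EV loading ratio. Edge significance in the
#' trafficking network uses 1000 permutations.
#'
#' @param detection_read_threshold Reads above which a miRNA counts as
#'   expressed (strict inequality). Default 5.
#' @param detection_umi_sum_threshold Minimum UMI sum across a group's
#'   replicates (inclusive). Default 10.
#' @param p_threshold Significance level for the age t-test. Default 0.05.
#' @param fc_threshold Fold-change bound used in compartment mode (>1.5 or
#'   <1/1.5). Default 1.5.
#' @param pcc_threshold Pearson correlation below which a miRNA-gene pair is
#'   anti-correlated. Default -0.2.
#' @param loading_fold_threshold Fold change of the EV loading ratio
#'   separating promoted/suppressed secretion (strict). Default 2.
#' @param n_permutations Edge randomizations for the network z-scores.
#' @param rng_seed Optional integer seed applied to stochastic stages.
#' @param pseudocount Added before logs and fold changes. Default 1.
#' @param group_rule How per-replicate read detection is summarized per
#'   (tissue, age) group: "mean" (default), "any" or "all".
#' @return An object of class \code{analysis_config}.
#' @export
analysis_config <- function(detection_read_threshold = 5,
                            detection_umi_sum_threshold = 10,
                            p_threshold = 0.05,
                            fc_threshold = 1.5,
                            pcc_threshold = -0.2,
                            loading_fold_threshold = 2,
                            n_permutations = 1000,
                            rng_seed = NULL,
                            pseudocount = 1,
                            group_rule = c("mean", "any", "all")) {
  group_rule <- match.arg(group_rule)
  stopifnot(
    detection_read_threshold >= 0,
    detection_umi_sum_threshold >= 0,
    p_threshold > 0, p_threshold < 1,
    fc_threshold > 1,
    loading_fold_threshold > 1,
    n_permutations >= 1,
    pseudocount > 0
  )
  structure(list(
    detection_read_threshold = detection_read_threshold,
    detection_umi_sum_threshold = detection_umi_sum_threshold,
    p_threshold = p_threshold,
    fc_threshold = fc_threshold,
    pcc_threshold = pcc_threshold,
    loading_fold_threshold = loading_fold_threshold,
    n_permutations = as.integer(n_permutations),
    rng_seed = rng_seed,
    pseudocount = pseudocount,
    group_rule = group_rule
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("mirflux analysis configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
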