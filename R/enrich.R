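#' Fraction of target genes annotated as ageing genes
#'
#' @param target_genes Character vector (or the \code{calls} data frame of
#'   \code{\link{call_targets}}) of target gene ids.
#' @param genage_list Character vector of ageing-annotated gene ids.
#' @return List with \code{fraction}, \code{n_targets}, \code{n_annotated}
#'   and the annotated \code{table}. Empty target set gives NA fraction
#'   with a warning.
#' @export
genage_fraction <- function(target_genes, genage_list) {
  if (is.data.frame(target_genes)) target_genes <- target_genes$gene_id
  genes <- unique(target_genes)
  if (length(genes) == 0) {
    warning("empty target set; GenAge fraction undefined")
    return(list(fraction = NA_real_, n_targets = 0L, n_annotated = 0L,
                table = data.frame(gene_id = character(), genage = logical())))
  }
  flag <- genes %in% genage_list
  list(fraction = mean(flag), n_targets = length(genes),
       n_annotated = sum(flag),
       table = data.frame(gene_id = genes, genage = flag, stringsAsFactors = FALSE))
}

#' One-sided category enrichment of target genes
#'
#' For every category at each of the three annotation levels, tests
#' over-representation of the target genes among the category's members
#' relative to the background by a one-sided Fisher's exact test
#' (alternative "greater"). Categories absent from the background are
#' skipped. Raw p-values are reported (significance at p < 0.05 by
#' convention) together with a BH FDR per level.
#'
#' @param target_genes Character vector of target gene ids.
#' @param background_genes Character vector containing all target genes.
#' @param annotation Data frame with \code{gene_id} and category columns
#'   \code{Category1}, \code{Category2}, \code{Category3} (missing levels
#'   are allowed).
#' @return Data frame: level, category, n_target_in, n_target,
#'   n_background_in, n_background, odds_ratio, p, fdr.
#' @export
category_enrichment <- function(target_genes, background_genes, annotation) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (!all(target_genes %in% background_genes)) {
    stop("background must contain every target gene")
  }
  levels_present <- intersect(c("Category1", "Category2", "Category3"),
                              names(annotation))
  if (length(levels_present) == 0) stop("annotation has no Category columns")
  annotation <- annotation[annotation$gene_id %in% background_genes, , drop = FALSE]
  n_t <- length(target_genes)
  n_b <- length(background_genes)
  rows <- list()
  for (lev in levels_present) {
    cats <- annotation[[lev]]
    for (cat in sort(unique(cats[!is.na(cats) & cats != ""]))) {
      members <- unique(annotation$gene_id[!is.na(cats) & cats == cat])
      if (length(members) == 0) next
      a <- sum(target_genes %in% members)          # target, in category
      b <- n_t - a                                 # target, not in category
      c_ <- length(members) - a                    # non-target bg, in category
      d <- (n_b - n_t) - c_                        # non-target bg, not in
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                        alternative = "greater")
      rows[[length(rows) + 1]] <- data.frame(
        level = lev, category = cat, n_target_in = a, n_target = n_t,
        n_background_in = length(members), n_background = n_b,
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  out$fdr <- ave(out$p, out$level, FUN = function(p) p.adjust(p, "BH"))
  out
}
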