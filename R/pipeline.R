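#' K-wise overlap report for named sets
#'
#' For every non-empty combination of the input sets, reports both the
#' plain intersection count (elements in all chosen sets) and the
#' exclusive Venn-region count (in all chosen sets and none of the
#' others), together with each combination's share of the union.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return Data frame: combination, degree, n_intersect, n_exclusive,
#'   pct_of_union; attribute \code{union_size}.
#' @export
overlap_report <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  nm <- names(sets)
  rows <- list()
  for (k in seq_along(sets)) {
    combos <- combn(nm, k, simplify = FALSE)
    for (cmb in combos) {
      inter <- Reduce(intersect, sets[cmb])
      excl <- setdiff(inter, unlist(sets[setdiff(nm, cmb)]))
      rows[[length(rows) + 1]] <- data.frame(
        combination = paste(cmb, collapse = "+"), degree = k,
        n_intersect = length(inter), n_exclusive = length(excl),
        pct_of_union = if (length(universe) > 0)
          100 * length(inter) / length(universe) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "union_size") <- length(universe)
  out
}

#' Overlap percentage of one set within another
#'
#' Percentage of \code{reference} members that are also in \code{other} —
#' e.g. the share of PITT-miRs that are Age-DEMIRs.
#'
#' @param reference,other Character vectors.
#' @param digits Rounding of the returned percentage; NULL keeps full
#'   precision. Default 1.
#' @return Percentage in \code{[0, 100]}.
#' @export
overlap_percentage <- function(reference, other, digits = 1) {
  reference <- unique(reference)
  if (length(reference) == 0) return(NA_real_)
  pct <- 100 * length(intersect(reference, other)) / length(reference)
  if (is.null(digits)) pct else round(pct, digits)
}

#' Shared-set decay across increasing numbers of sets
#'
#' Number of elements present in at least k of the sets, for k = 1..K;
#' non-increasing in k by construction (the profile behind "shared
#' elements decrease as more tissues are intersected").
#'
#' @param sets Named list of character vectors.
#' @return Data frame: k, n_shared.
#' @export
shared_set_decay <- function(sets) {
  counts <- table(unlist(lapply(sets, unique)))
  data.frame(k = seq_along(sets),
             n_shared = vapply(seq_along(sets),
                               function(k) sum(counts >= k), integer(1)))
}

#' Run the full analysis pipeline on a dataset
#'
#' Composes every stage on a synthetic dataset (or a fixture read back
#' from disk): normalization and detection, ordination QC, per-tissue
#' age differential expression (Age-DEMIRs) with overlap summaries, T/E
#' contrast and PITT classification, permutation-tested trafficking
#' networks per age with replicate-level flow counts, worm/EV detection,
#' compartment differential expression, loading ratios and secretion
#' classes, seed-site plus anti-correlation target calling with the
#' autonomy partition, GenAge fractions and category enrichment. Also
#' assembles the headline filter-cascade counts.
#'
#' @param data A \code{mirflux_sim} (from \code{\link{simulate_mirnaome}}
#'   or \code{\link{read_fixture}}).
#' @param cfg An \code{\link{analysis_config}}.
#' @return A list of stage outputs plus \code{counts}, the named cascade
#'   summary.
#' @export
run_all <- function(data, cfg = analysis_config()) {
  stopifnot(inherits(data, "mirflux_sim"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  out <- list(cfg = cfg)

  ## normalization + detection + QC
  tpm <- compute_tpm(data$tissue_counts)
  qnorm <- log2_quantile_normalize(tpm, cfg$pseudocount)
  detection <- call_detection_reads(data$tissue_counts,
                                    threshold = cfg$detection_read_threshold,
                                    group_rule = cfg$group_rule)
  out$tpm <- tpm; out$qnorm <- qnorm; out$detection <- detection
  out$qc <- ordination_qc(qnorm)
  detected <- rownames(detection$per_group)[apply(detection$per_group, 1, any, na.rm = TRUE)]
  gene_of <- setNames(data$annotation$gene_id, data$annotation$mature_id)

  ## age differential expression per tissue
  de <- call_age_demirs(tpm, detection, cfg, mode = "tissue")
  out$de <- de
  demir_sets <- lapply(de$demirs$per_tissue, function(s) c(s$up, s$down))
  out$demir_overlap <- if (length(demir_sets) >= 2) overlap_report(demir_sets) else NULL
  out$demir_decay <- shared_set_decay(demir_sets)
  conserved <- data$annotation$conserved_in_mammals[
    match(de$demirs$union, data$annotation$mature_id)]

  ## T/E contrast, PITT-miRs, trafficking networks
  profiles <- te_profiles(detection, data$tmap, data$annotation)
  pitt <- classify_pitt(profiles)
  out$pitt <- pitt
  nets <- lapply(setNames(profiles$ages, profiles$ages), function(a) {
    permutation_flow_test(build_trafficking_network(profiles, a),
                          n_perm = cfg$n_permutations, seed = cfg$rng_seed)
  })
  out$networks <- nets
  out$flows <- flow_summary(data$tissue_counts, data$tmap, data$annotation,
                            threshold = cfg$detection_read_threshold)

  ## worm/EV compartments
  umi_detection <- call_detection_umi(data$umi_counts,
                                      threshold = cfg$detection_umi_sum_threshold)
  out$umi_detection <- umi_detection
  umi_rel <- compute_tpm(data$umi_counts)  # per-million share per library
  ev_de <- call_age_demirs(umi_rel, umi_detection, cfg, mode = "compartment")
  out$ev_de <- ev_de
  rel <- relative_abundance(data$umi_counts, umi_detection)
  lr <- loading_ratio(rel)
  secretion <- classify_secretion(lr, cfg$loading_fold_threshold)
  out$relative_abundance <- rel
  out$loading <- secretion$table
  out$secretion <- secretion

  ev_detected <- rownames(umi_detection$per_group)[
    vapply(rownames(umi_detection$per_group),
           function(m) isTRUE(umi_detection$per_group[m, "EV", "D1"]) ||
             isTRUE(umi_detection$per_group[m, "EV", "D8"]), logical(1))]
  worm_detected <- rownames(umi_detection$per_group)[
    vapply(rownames(umi_detection$per_group),
           function(m) isTRUE(umi_detection$per_group[m, "Worm", "D1"]) ||
             isTRUE(umi_detection$per_group[m, "Worm", "D8"]), logical(1))]

  ## targets, autonomy, enrichment
  counts <- list(
    n_matures_identified = length(detected),
    n_genes_identified = length(unique(gene_of[detected])),
    n_age_demirs = length(de$demirs$union),
    pct_demir_conserved = if (length(conserved) > 0) 100 * mean(conserved) else NA,
    n_analysable_matures = dim(profiles$E)[1],
    n_analysable_genes = length(unique(profiles$annotation$gene_id)),
    n_pitt = length(pitt$pitt),
    n_pitt_age_demir = length(intersect(pitt$pitt, de$demirs$union)),
    pct_pitt_age_demir = overlap_percentage(pitt$pitt, de$demirs$union),
    n_ev_detected = length(ev_detected),
    n_worm_detected = length(worm_detected),
    n_pitt_in_ev = length(intersect(pitt$pitt, ev_detected)),
    n_ev_de_up = sum(ev_de$results$direction == "up" &
                       ev_de$results$tissue == "EV"),
    n_ev_de_down = sum(ev_de$results$direction == "down" &
                         ev_de$results$tissue == "EV"),
    n_secretion_promoted = unname(secretion$counts["promoted"]),
    n_secretion_suppressed = unname(secretion$counts["suppressed"]))

  if (!is.null(data$mrna)) {
    sites <- find_all_seed_sites(data$utr_seqs, data$mirna_seqs)
    mrna_detection <- call_detection_reads(data$mrna,
                                           threshold = cfg$detection_read_threshold,
                                           group_rule = cfg$group_rule)
    targets <- call_targets(tpm, data$mrna, sites, detection, mrna_detection,
                            pitt, cfg)
    out$sites <- sites
    out$targets <- targets
    calls <- targets$calls
    out$target_counts <- if (nrow(calls) > 0) {
      aggregate(gene_id ~ tissue + age, calls,
                FUN = function(g) length(unique(g)))
    } else data.frame()
    out$autonomy_fractions <- if (nrow(calls) > 0) {
      ag <- aggregate(autonomy ~ tissue + age, calls,
                      FUN = function(a) mean(a == "non_autonomous"))
      names(ag)[3] <- "frac_non_autonomous"
      ag
    } else data.frame()
    demir_calls <- calls[calls$mature_id %in% de$demirs$union, , drop = FALSE]
    out$genage <- genage_fraction(unique(calls$gene_id), data$genage)
    out$genage_demir <- genage_fraction(unique(demir_calls$gene_id), data$genage)
    if (!is.null(data$wormcat) && nrow(demir_calls) > 0) {
      background <- unique(rownames(data$mrna$values)[
        apply(mrna_detection$per_group, 1, any, na.rm = TRUE)])
      out$enrichment <- category_enrichment(
        intersect(unique(demir_calls$gene_id), background), background, data$wormcat)
    }
    counts$n_target_genes <- length(unique(calls$gene_id))
    counts$n_demir_target_genes <- length(unique(demir_calls$gene_id))
    counts$pct_targets_non_autonomous <- if (nrow(calls) > 0)
      100 * mean(calls$autonomy == "non_autonomous") else NA
    counts$pct_demir_targets_genage <- if (!is.null(out$genage_demir))
      100 * out$genage_demir$fraction else NA
  }
  out$counts <- counts
  out
}

#' Write the pipeline report bundle to a directory
#'
#' Emits tidy TSVs for every stage output of \code{\link{run_all}} plus a
#' two-column key/value cascade-count summary.
#'
#' @param res Result of \code{\link{run_all}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  wt <- function(d, f) write.table(d, fp(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(res$de$results, "age_de.tsv")
  wt(res$pitt$table, "pitt.tsv")
  for (a in names(res$networks)) {
    wt(res$networks[[a]]$edges, sprintf("network_%s.tsv", a))
  }
  wt(res$flows, "flows_replicate.tsv")
  wt(res$loading, "ev_loading.tsv")
  wt(res$ev_de$results, "ev_de.tsv")
  if (!is.null(res$demir_overlap)) wt(res$demir_overlap, "demir_overlap.tsv")
  wt(res$demir_decay, "demir_shared_decay.tsv")
  if (!is.null(res$targets)) {
    wt(res$targets$pairs, "target_pairs.tsv")
    wt(res$targets$calls, "target_calls.tsv")
    if (!is.null(res$autonomy_fractions) && nrow(res$autonomy_fractions) > 0) {
      wt(res$autonomy_fractions, "autonomy_fractions.tsv")
    }
    if (!is.null(res$enrichment)) wt(res$enrichment, "enrichment.tsv")
  }
  counts <- res$counts
  wt(data.frame(quantity = names(counts),
                value = vapply(counts, function(v) format(v), character(1))),
     "cascade_counts.tsv")
  invisible(dir)
}
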