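RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

reverse_complement_rna <- function(x) {
  chars <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(RNA_COMP[chars], collapse = "")
}

#' Find canonical seed-match sites in 3'UTRs
#'
#' Scans UTR sequences (RNA alphabet, 5'->3') for canonical sites of one
#' mature miRNA. A site is anchored on the 6-nt core complementary to
#' miRNA positions 2-7; the flanking positions decide the type: a match to
#' position 8 on the 5' side and an A opposite position 1 on the 3' side
#' give an 8mer, the position-8 match alone a 7mer-m8, the A alone a
#' 7mer-A1. Each core occurrence (overlapping occurrences included) is
#' reported once, as its strongest type. Positions are 1-based inclusive
#' on the given UTR.
#'
#' @param utrs Named character vector of UTR sequences (A/C/G/U).
#' @param mirna Mature miRNA sequence (A/C/G/U, length >= 8).
#' @param mature_id Id recorded in the output. Default "mirna".
#' @return Data frame: gene_id, mature_id, site_type, utr_start, utr_end.
#' @export
find_seed_sites <- function(utrs, mirna, mature_id = "mirna") {
  if (is.null(names(utrs))) names(utrs) <- paste0("utr", seq_along(utrs))
  if (nchar(mirna) < 8) stop("miRNA sequence must be at least 8 nt")
  if (grepl("[^ACGU]", mirna) || any(grepl("[^ACGU]", utrs))) {
    stop("sequences must be over the RNA alphabet A/C/G/U")
  }
  seed7 <- reverse_complement_rna(substr(mirna, 2, 8))  # 5'->3' site for pos 2-8
  m8 <- substr(seed7, 1, 1)
  core6 <- substr(seed7, 2, 7)
  # zero-width lookahead finds overlapping core occurrences
  hits <- stringi::stri_locate_all_regex(utrs, paste0("(?=", core6, ")"))
  out <- vector("list", length(utrs))
  for (i in seq_along(utrs)) {
    starts <- hits[[i]][, 1]
    if (length(starts) == 0 || is.na(starts[1])) next
    utr <- utrs[[i]]
    len <- nchar(utr)
    left <- ifelse(starts > 1, substr(rep(utr, length(starts)), starts - 1, starts - 1), "")
    right <- ifelse(starts + 6 <= len, substr(rep(utr, length(starts)), starts + 6, starts + 6), "")
    m8_ok <- left == m8
    a1_ok <- right == "A"
    type <- ifelse(m8_ok & a1_ok, "8mer",
            ifelse(m8_ok, "7mer-m8",
            ifelse(a1_ok, "7mer-A1", NA_character_)))
    keep <- !is.na(type)
    if (!any(keep)) next
    s <- ifelse(m8_ok, starts - 1L, starts)[keep]
    e <- ifelse(a1_ok, starts + 6L, starts + 5L)[keep]
    out[[i]] <- data.frame(gene_id = names(utrs)[i], mature_id = mature_id,
                           site_type = type[keep], utr_start = s, utr_end = e,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(gene_id = character(), mature_id = character(),
                      site_type = character(), utr_start = integer(),
                      utr_end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @rdname find_seed_sites
#' @param mirnas Named character vector of mature miRNA sequences.
#' @return \code{find_all_seed_sites}: row-bound site table over all miRNAs.
#' @export
find_all_seed_sites <- function(utrs, mirnas) {
  do.call(rbind, lapply(names(mirnas), function(m) {
    find_seed_sites(utrs, mirnas[[m]], mature_id = m)
  }))
}

#' Pearson anti-correlation between matched expression vectors
#'
#' @param mirna_expr,gene_expr Numeric vectors matched by condition
#'   (length >= 3).
#' @return Pearson r, or NA with attribute \code{reason} when a vector is
#'   constant.
#' @export
anticorrelation <- function(mirna_expr, gene_expr) {
  if (length(mirna_expr) != length(gene_expr)) {
    stop("vectors must be matched: lengths ", length(mirna_expr), " vs ",
         length(gene_expr))
  }
  if (length(mirna_expr) < 3) stop("need at least 3 matched conditions")
  if (sd(mirna_expr) == 0 || sd(gene_expr) == 0) {
    return(structure(NA_real_, reason = "constant_vector"))
  }
  cor(mirna_expr, gene_expr)
}

condition_means <- function(x, conditions, pseudocount) {
  logged <- x$scale %in% c("log2tpm", "qnorm_log2tpm")
  v <- if (logged) x$values else log2(x$values + pseudocount)
  sapply(seq_len(nrow(conditions)), function(i) {
    j <- which(x$samples$tissue == conditions$tissue[i] &
               x$samples$age == conditions$age[i])
    rowMeans(v[, j, drop = FALSE])
  })
}

#' Call miRNA targets from anti-correlation and seed sites
#'
#' A miRNA-gene pair is a target pair when its Pearson correlation across
#' the tissue-by-age condition means of log2 expression falls below the
#' threshold (default -0.2) and the gene's 3'UTR carries at least one
#' canonical seed site. The pair is then called in every (tissue, age)
#' where both the miRNA and the gene are expressed; the call is
#' non-autonomous when the miRNA is PITT in that tissue-age (transported
#' in), autonomous otherwise.
#'
#' @param mirna_x,mrna_x \code{ExpressionMatrix} objects sharing
#'   tissue/age conditions.
#' @param sites Site table from \code{\link{find_all_seed_sites}} (or an
#'   external TargetScan-style table with the same columns).
#' @param mirna_detection,mrna_detection \code{DetectionTable}s.
#' @param pitt Output of \code{\link{classify_pitt}}.
#' @param cfg \code{analysis_config} (uses pcc_threshold, pseudocount).
#' @return List with \code{pairs} (per miRNA-gene pair: pcc, n_sites,
#'   site_types, passed, reason) and \code{calls} (per pair x tissue x
#'   age: pcc, site_types, autonomy).
#' @export
call_targets <- function(mirna_x, mrna_x, sites, mirna_detection,
                         mrna_detection, pitt, cfg = analysis_config()) {
  stopifnot(inherits(mirna_x, "ExpressionMatrix"), inherits(mrna_x, "ExpressionMatrix"))
  conds <- unique(rbind(mirna_x$samples[, c("tissue", "age")],
                        mrna_x$samples[, c("tissue", "age")]))
  conds <- conds[conds$tissue %in% unique(mirna_x$samples$tissue) &
                 conds$tissue %in% unique(mrna_x$samples$tissue), , drop = FALSE]
  if (nrow(conds) < 3) stop("need at least 3 shared tissue-age conditions")
  M <- condition_means(mirna_x, conds, cfg$pseudocount)
  G <- condition_means(mrna_x, conds, cfg$pseudocount)
  pairs <- unique(sites[, c("mature_id", "gene_id")])
  pairs <- pairs[pairs$mature_id %in% rownames(M) & pairs$gene_id %in% rownames(G), ]
  site_info <- split(sites, paste(sites$mature_id, sites$gene_id))
  pcc <- numeric(nrow(pairs)); reason <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- anticorrelation(M[pairs$mature_id[i], ], G[pairs$gene_id[i], ])
    pcc[i] <- r
    reason[i] <- if (is.na(r)) attr(r, "reason") else "ok"
  }
  key <- paste(pairs$mature_id, pairs$gene_id)
  pairs$pcc <- pcc
  pairs$n_sites <- vapply(site_info[key], nrow, integer(1))
  pairs$site_types <- vapply(site_info[key], function(d)
    paste(sort(unique(d$site_type)), collapse = ";"), character(1))
  pairs$passed <- !is.na(pcc) & pcc < cfg$pcc_threshold
  pairs$reason <- ifelse(pairs$passed, "ok",
                  ifelse(reason != "ok", reason, "pcc_above_threshold"))
  rownames(pairs) <- NULL
  pitt_key <- with(pitt$table, paste(mature_id, tissue, age))
  pitt_lookup <- setNames(pitt$table$pitt, pitt_key)
  calls <- list()
  hits <- pairs[pairs$passed, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    m <- hits$mature_id[i]; g <- hits$gene_id[i]
    for (ci in seq_len(nrow(conds))) {
      t <- conds$tissue[ci]; a <- conds$age[ci]
      em <- mirna_detection$per_group[m, t, a]
      eg <- mrna_detection$per_group[g, t, a]
      if (is.na(em) || is.na(eg) || !em || !eg) next
      is_pitt <- isTRUE(pitt_lookup[paste(m, t, a)])
      calls[[length(calls) + 1]] <- data.frame(
        mature_id = m, gene_id = g, tissue = t, age = a,
        pcc = hits$pcc[i], site_types = hits$site_types[i],
        autonomy = if (is_pitt) "non_autonomous" else "autonomous",
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls) > 0) do.call(rbind, calls) else
    data.frame(mature_id = character(), gene_id = character(),
               tissue = character(), age = character(), pcc = numeric(),
               site_types = character(), autonomy = character(),
               stringsAsFactors = FALSE)
  list(pairs = pairs, calls = calls)
}
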