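#' Generator configuration for synthetic study data
#'
#' Parameters of the synthetic-data generator emulating the study design:
#' five somatic tissues sampled at day 1 and day 8 of adulthood with three
#' replicates of small-RNA counts each, whole-worm and EV UMI libraries,
#' promoter-activity transcription maps, planted inter-tissue transport
#' events, age effects, EV sorting weights, and anti-correlated target
#' genes whose generated 3'UTRs carry canonical seed sites.
#'
#' @param n_mirnas Number of mature miRNAs. Default 60.
#' @param n_genes Number of protein-coding genes (0 skips the mRNA/UTR
#'   layer). Default 300.
#' @param tissues,ages,n_replicates Study design; defaults five tissues,
#'   D1/D8, three replicates.
#' @param nb_dispersion Negative-binomial dispersion of read counts
#'   (variance mu + dispersion * mu^2). Default 0.1.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline of
#'   per-miRNA expression levels. Defaults log(300) and 1.
#' @param min_expression Floor on the expected level wherever a miRNA is
#'   expressed, keeping expressed entries above the read-detection
#'   threshold. Default 50.
#' @param frac_age_dependent Fraction of miRNAs with a planted age effect.
#'   Default 0.3.
#' @param promoter_age_change_frac Fraction of miRNA genes whose promoter
#'   activity gains or loses one tissue at D8 (age-dependent
#'   transcription). Default 0.15.
#' @param age_effect_fold Fold change of planted age effects. Default 4.
#' @param frac_transported Fraction of miRNAs planted as inter-tissue
#'   transported. Default 0.5.
#' @param transport_level_frac Receiver-tissue level as a fraction of the
#'   mean source level (transported miRNAs sit lower than at their
#'   source). Default 0.2.
#' @param transport_age_overlap Probability that a transport event is
#'   present at both ages (otherwise one age). Default 0.6.
#' @param sorting_weight_log_sd Log-normal spread of EV sorting weights.
#'   Default 1.
#' @param frac_secretion_promoted,frac_secretion_suppressed Fractions of
#'   miRNAs whose D8 sorting weight is boosted/reduced. Defaults 0.3 each.
#' @param d8_sorting_shift Fold applied to the D8 weight of the promoted
#'   set (its reciprocal for the suppressed set). Default 3.
#' @param umi_total Expected UMI yield per library. Default 30000.
#' @param mrna_log_mean,mrna_log_sd Log-normal baseline of gene expression.
#' @param mrna_noise_log_sd Replicate-level log-normal noise of the mRNA
#'   matrix. Default 0.25.
#' @param n_target_pairs Planted miRNA-target pairs. Default 100.
#' @param target_strength Log2 depression of a target gene per standard
#'   deviation of its miRNA's cross-condition profile. Default 1.5.
#' @param utr_length Length of generated 3'UTRs. Default 300.
#' @param noiseless Deterministic expected values instead of sampled
#'   counts (used for exact-recovery checks). Default FALSE.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n_mirnas = 60, n_genes = 300,
                             tissues = worm_tissues(), ages = worm_ages(),
                             n_replicates = 3,
                             nb_dispersion = 0.1,
                             baseline_log_mean = log(300), baseline_log_sd = 1,
                             min_expression = 50,
                             frac_age_dependent = 0.3, age_effect_fold = 4,
                             promoter_age_change_frac = 0.15,
                             frac_transported = 0.5,
                             transport_level_frac = 0.2,
                             transport_age_overlap = 0.6,
                             sorting_weight_log_sd = 1,
                             frac_secretion_promoted = 0.3,
                             frac_secretion_suppressed = 0.3,
                             d8_sorting_shift = 3,
                             umi_total = 30000,
                             mrna_log_mean = log(200), mrna_log_sd = 1,
                             mrna_noise_log_sd = 0.25,
                             n_target_pairs = 100,
                             target_strength = 1.5,
                             utr_length = 300,
                             noiseless = FALSE,
                             seed = NULL) {
  fracs <- c(frac_age_dependent, frac_transported, transport_age_overlap,
             frac_secretion_promoted, frac_secretion_suppressed,
             promoter_age_change_frac)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            frac_secretion_promoted + frac_secretion_suppressed <= 1,
            age_effect_fold > 0, d8_sorting_shift > 0,
            transport_level_frac > 0, nb_dispersion >= 0,
            n_mirnas >= 1, n_genes >= 0, n_replicates >= 1,
            length(ages) == 2, utr_length >= 50)
  if (frac_transported > 0 && length(tissues) < 2) {
    stop("transport requires at least two tissues")
  }
  if (n_target_pairs > n_genes) stop("n_target_pairs cannot exceed n_genes")
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# mature sequences with pairwise-distinct position 2-7 hexamers, so planted
# sites are unambiguous between miRNAs
generate_mature_seqs <- function(ids) {
  seen <- character(0)
  seqs <- character(length(ids))
  for (i in seq_along(ids)) {
    repeat {
      s <- random_rna(22)
      hex <- substr(s, 2, 7)
      if (!(hex %in% seen)) break
    }
    seen <- c(seen, substr(s, 2, 7))
    seqs[i] <- s
  }
  setNames(seqs, ids)
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Emulates the study's data layers: negative-binomial tissue read counts
#' around per-(miRNA, tissue, age) expected levels driven by a planted
#' transcription map, transport events and age effects; multinomial UMI
#' counts for whole-worm and EV libraries with planted sorting weights;
#' a pre-normalized mRNA matrix in which planted target genes decrease
#' with their miRNA's level; and generated 3'UTRs carrying planted
#' canonical seed sites (accidental sites for panel miRNAs are scrubbed by
#' point mutation). Deterministic for a fixed seed.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return A \code{mirflux_sim} list: \code{tissue_counts},
#'   \code{umi_counts}, \code{mrna} (\code{ExpressionMatrix}s),
#'   \code{mirna_seqs}, \code{utr_seqs}, \code{tmap}, \code{annotation},
#'   \code{genage}, \code{wormcat}, and \code{truth} (transport events,
#'   planted Age-DEMIRs, sorting weights, target pairs, expected levels).
#' @export
simulate_mirnaome <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tissues <- cfg$tissues
  ages <- cfg$ages
  K <- length(tissues)

  ## --- annotation: genes, arms, families -------------------------------
  gene_ids <- character(0); mature_ids <- character(0)
  gene_of <- character(0); arm_of <- character(0)
  gi <- 0
  while (length(mature_ids) < cfg$n_mirnas) {
    gi <- gi + 1
    g <- sprintf("sim-mir-%d", gi)
    arms <- if (length(mature_ids) + 2 <= cfg$n_mirnas && runif(1) < 0.25) {
      c("3p", "5p")
    } else "3p"
    for (a in arms) {
      mature_ids <- c(mature_ids, sprintf("sim-miR-%d-%s", gi, a))
      gene_of <- c(gene_of, g)
      arm_of <- c(arm_of, a)
    }
    gene_ids <- c(gene_ids, g)
  }
  annotation <- data.frame(
    mature_id = mature_ids, gene_id = gene_of,
    family_id = sprintf("sim-fam-%d", (match(gene_of, gene_ids) + 1) %/% 2),
    arm = arm_of,
    conserved_in_mammals = runif(length(mature_ids)) < 0.5,
    stringsAsFactors = FALSE)
  mirna_seqs <- generate_mature_seqs(mature_ids)
  annotation$mature_sequence <- unname(mirna_seqs[annotation$mature_id])
  M <- length(mature_ids)

  ## --- transcription map (gene level, age-specific) --------------------
  calls <- array(FALSE, dim = c(length(gene_ids), K, 2),
                 dimnames = list(gene_ids, tissues, ages))
  for (g in gene_ids) {
    n_src <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    src <- sample(tissues, n_src)
    calls[g, src, 1] <- TRUE
    calls[g, src, 2] <- TRUE
    if (runif(1) < cfg$promoter_age_change_frac) {  # age-dependent promoter activity
      if (n_src < K && runif(1) < 0.5) {
        calls[g, sample(setdiff(tissues, src), 1), 2] <- TRUE
      } else if (n_src > 1) {
        calls[g, sample(src, 1), 2] <- FALSE
      }
    }
  }
  tmap <- transcription_map(calls)

  ## --- expected levels: transcription, age effects, transport ----------
  level <- array(0, dim = c(M, K, 2), dimnames = list(mature_ids, tissues, ages))
  base <- pmax(rlnorm(M, cfg$baseline_log_mean, cfg$baseline_log_sd),
               cfg$min_expression)
  tissue_factor <- matrix(rlnorm(M * K, 0, 0.3), M, K,
                          dimnames = list(mature_ids, tissues))
  for (i in seq_len(M)) {
    g <- gene_of[i]
    for (a in 1:2) {
      on <- calls[g, , a]
      level[i, on, a] <- base[i] * tissue_factor[i, on]
    }
  }

  n_de <- round(cfg$frac_age_dependent * M)
  de_mirnas <- if (n_de > 0) sample(mature_ids, n_de) else character(0)
  demir_rows <- list()
  for (m in de_mirnas) {
    g <- gene_of[match(m, mature_ids)]
    stable <- tissues[calls[g, , 1] & calls[g, , 2]]
    if (length(stable) == 0) next
    affected <- stable[runif(length(stable)) < 0.7]
    if (length(affected) == 0) affected <- sample(stable, 1)
    dir <- sample(c("up", "down"), 1)
    fold <- if (dir == "up") cfg$age_effect_fold else 1 / cfg$age_effect_fold
    level[m, affected, 2] <- level[m, affected, 2] * fold
    demir_rows[[length(demir_rows) + 1]] <- data.frame(
      mature_id = m, tissue = affected, direction = dir, fold = fold,
      stringsAsFactors = FALSE)
  }
  age_demir_truth <- if (length(demir_rows) > 0) do.call(rbind, demir_rows) else
    data.frame(mature_id = character(), tissue = character(),
               direction = character(), fold = numeric())

  n_tr <- round(cfg$frac_transported * M)
  transport_rows <- list()
  if (n_tr > 0) {
    src_union <- lapply(seq_len(M), function(i) {
      g <- gene_of[i]; tissues[calls[g, , 1] | calls[g, , 2]]
    })
    eligible <- which(vapply(src_union, length, integer(1)) < K)
    chosen <- sample(eligible, min(n_tr, length(eligible)))
    for (i in chosen) {
      m <- mature_ids[i]
      free <- setdiff(tissues, src_union[[i]])
      receivers <- sample(free, min(length(free), sample(1:2, 1)))
      ev_ages <- if (runif(1) < cfg$transport_age_overlap) ages else sample(ages, 1)
      for (a in ev_ages) {
        ai <- match(a, ages)
        src_a <- tissues[calls[gene_of[i], , ai]]
        if (length(src_a) == 0) next
        level[m, receivers, ai] <- cfg$transport_level_frac *
          mean(level[m, src_a, ai])
        transport_rows[[length(transport_rows) + 1]] <- data.frame(
          mature_id = m, age = a,
          sources = paste(src_a, collapse = ";"),
          receivers = paste(receivers, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  transport_events <- if (length(transport_rows) > 0) do.call(rbind, transport_rows) else
    data.frame(mature_id = character(), age = character(),
               sources = character(), receivers = character())

  ## --- tissue read counts ----------------------------------------------
  reps <- seq_len(cfg$n_replicates)
  t_samples <- expand.grid(replicate = reps, age = ages, tissue = tissues,
                           stringsAsFactors = FALSE)[, c("tissue", "age", "replicate")]
  t_samples$sample_id <- sprintf("%s_%s_r%d", t_samples$tissue, t_samples$age,
                                 t_samples$replicate)
  t_samples$count_unit <- "reads"
  counts <- matrix(0, M, nrow(t_samples),
                   dimnames = list(mature_ids, t_samples$sample_id))
  for (j in seq_len(nrow(t_samples))) {
    mu <- level[, t_samples$tissue[j], match(t_samples$age[j], ages)]
    sf <- if (cfg$noiseless) 1 else rlnorm(1, 0, 0.1)
    counts[, j] <- if (cfg$noiseless || cfg$nb_dispersion == 0) {
      round(mu * sf)
    } else {
      rnbinom(M, mu = mu * sf, size = 1 / cfg$nb_dispersion)
    }
  }
  tissue_counts <- expression_matrix(counts, t_samples, scale = "raw_count")

  ## --- worm + EV UMI counts with sorting weights -----------------------
  worm_level <- apply(level, c(1, 3), sum)           # mature x age
  worm_share <- sweep(worm_level, 2, colSums(worm_level), "/")
  w_base <- rlnorm(M, 0, cfg$sorting_weight_log_sd)
  cls <- rep("stable", M)
  n_pro <- round(cfg$frac_secretion_promoted * M)
  n_sup <- round(cfg$frac_secretion_suppressed * M)
  shifted <- sample(M, n_pro + n_sup)
  cls[shifted[seq_len(n_pro)]] <- "promoted"
  cls[shifted[n_pro + seq_len(n_sup)]] <- "suppressed"
  shift <- c(promoted = cfg$d8_sorting_shift, stable = 1,
             suppressed = 1 / cfg$d8_sorting_shift)[cls]
  weight <- cbind(D1 = w_base, D8 = w_base * shift)
  rownames(weight) <- mature_ids
  # normalize so the worm-share-weighted mean weight is 1 per age: the EV
  # loading ratio then recovers the planted weight directly
  for (a in 1:2) weight[, a] <- weight[, a] / sum(worm_share[, a] * weight[, a])
  ev_share <- worm_share * weight
  ev_share <- sweep(ev_share, 2, colSums(ev_share), "/")
  # EV composition is a share vector, so boosting many miRNAs compresses
  # everyone's ratio: the realized secretion class follows the normalized
  # weight ratio, the nominal shift class records the mechanism
  realized <- ifelse(weight[, 2] / weight[, 1] > 2, "promoted",
              ifelse(weight[, 2] / weight[, 1] < 0.5, "suppressed", "stable"))

  u_samples <- expand.grid(replicate = reps, age = ages,
                           tissue = c("Worm", "EV"),
                           stringsAsFactors = FALSE)[, c("tissue", "age", "replicate")]
  u_samples$sample_id <- sprintf("%s_%s_r%d", u_samples$tissue, u_samples$age,
                                 u_samples$replicate)
  u_samples$count_unit <- "UMI"
  umi <- matrix(0, M, nrow(u_samples),
                dimnames = list(mature_ids, u_samples$sample_id))
  for (j in seq_len(nrow(u_samples))) {
    share <- if (u_samples$tissue[j] == "Worm") {
      worm_share[, u_samples$age[j]]
    } else {
      ev_share[, u_samples$age[j]]
    }
    if (cfg$noiseless) {
      umi[, j] <- round(share * cfg$umi_total)
    } else {
      n_tot <- round(cfg$umi_total * rlnorm(1, 0, 0.1))
      umi[, j] <- rmultinom(1, n_tot, share)
    }
  }
  umi_counts <- expression_matrix(umi, u_samples, scale = "raw_count")
  sorting_weights <- data.frame(mature_id = mature_ids,
                                weight_d1 = weight[, 1], weight_d8 = weight[, 2],
                                secretion_class = realized, shift_class = cls,
                                stringsAsFactors = FALSE)
  rownames(sorting_weights) <- NULL

  ## --- mRNA matrix, target pairs, UTRs ---------------------------------
  mrna <- NULL; utr_seqs <- NULL; wormcat <- NULL; genage <- character(0)
  target_pairs <- data.frame(mature_id = character(), gene_id = character(),
                             n_sites = integer(), site_types = character())
  if (cfg$n_genes > 0) {
    pc_genes <- sprintf("sim-gene-%d", seq_len(cfg$n_genes))
    g_base <- rlnorm(cfg$n_genes, cfg$mrna_log_mean, cfg$mrna_log_sd)
    g_tissue <- matrix(rlnorm(cfg$n_genes * K, 0, 0.3), cfg$n_genes, K,
                       dimnames = list(pc_genes, tissues))
    gene_mean <- array(rep(g_base * g_tissue, 2), dim = c(cfg$n_genes, K, 2),
                       dimnames = list(pc_genes, tissues, ages))
    target_gene_idx <- integer(0)
    if (cfg$n_target_pairs > 0) {
      target_gene_idx <- sample(cfg$n_genes, cfg$n_target_pairs)
      target_mirna <- sample(mature_ids, cfg$n_target_pairs, replace = TRUE)
      # depress each target gene by target_strength log2 units per SD of
      # its miRNA's standardized cross-condition profile
      log_prof <- log2(matrix(level, M, K * 2) + 1)
      prof_sd <- apply(log_prof, 1, sd)
      for (p in seq_len(cfg$n_target_pairs)) {
        mi <- match(target_mirna[p], mature_ids)
        if (prof_sd[mi] == 0) next
        z <- (log_prof[mi, ] - mean(log_prof[mi, ])) / prof_sd[mi]
        gene_mean[target_gene_idx[p], , ] <-
          gene_mean[target_gene_idx[p], , ] * 2^(-cfg$target_strength * z)
      }
      target_pairs <- data.frame(mature_id = target_mirna,
                                 gene_id = pc_genes[target_gene_idx],
                                 stringsAsFactors = FALSE)
    }
    g_values <- matrix(0, cfg$n_genes, nrow(t_samples),
                       dimnames = list(pc_genes, t_samples$sample_id))
    for (j in seq_len(nrow(t_samples))) {
      mu <- gene_mean[, t_samples$tissue[j], match(t_samples$age[j], ages)]
      g_values[, j] <- if (cfg$noiseless) mu else
        mu * rlnorm(cfg$n_genes, 0, cfg$mrna_noise_log_sd)
    }
    mrna <- expression_matrix(g_values, t_samples, scale = "tpm")

    utr <- plant_utrs(pc_genes, target_pairs, mirna_seqs, cfg$utr_length)
    utr_seqs <- utr$seqs
    target_pairs <- utr$target_pairs

    # annotations: ageing genes enriched among targets, one planted
    # over-represented category
    is_target <- pc_genes %in% target_pairs$gene_id
    genage <- pc_genes[runif(cfg$n_genes) < ifelse(is_target, 0.25, 0.1)]
    cat1_pool <- c("Metabolism", "Proteolysis", "Stress response", "Signaling",
                   "Development", "Neuronal function", "Transcription", "Unknown")
    cat1 <- ifelse(is_target & runif(cfg$n_genes) < 0.45, "Metabolism",
                   sample(cat1_pool, cfg$n_genes, replace = TRUE))
    wormcat <- data.frame(
      gene_id = pc_genes,
      Category1 = cat1,
      Category2 = paste0(cat1, ": sub", sample(1:3, cfg$n_genes, replace = TRUE)),
      stringsAsFactors = FALSE)
    wormcat$Category3 <- paste0(wormcat$Category2, ".",
                                sample(1:2, cfg$n_genes, replace = TRUE))
  }

  structure(list(
    cfg = cfg,
    tissue_counts = tissue_counts,
    umi_counts = umi_counts,
    mrna = mrna,
    mirna_seqs = mirna_seqs,
    utr_seqs = utr_seqs,
    tmap = tmap,
    annotation = annotation,
    genage = genage,
    wormcat = wormcat,
    truth = list(
      level = level,
      worm_share = worm_share,
      ev_share = ev_share,
      transport_events = transport_events,
      age_demirs = age_demir_truth,
      sorting_weights = sorting_weights,
      target_pairs = target_pairs)
  ), class = "mirflux_sim")
}

# random UTRs with planted canonical sites for the target pairs; accidental
# 2-7 core matches of any panel miRNA outside planted ranges are removed by
# point mutation
plant_utrs <- function(pc_genes, target_pairs, mirna_seqs, utr_length) {
  seqs <- setNames(vapply(pc_genes, function(g) random_rna(utr_length),
                          character(1)), pc_genes)
  protected <- lapply(seqs, function(s) matrix(integer(0), ncol = 2))
  site_rows <- list()
  bases <- c("A", "C", "G", "U")
  if (nrow(target_pairs) > 0) {
    for (p in seq_len(nrow(target_pairs))) {
      g <- target_pairs$gene_id[p]
      mir <- mirna_seqs[[target_pairs$mature_id[p]]]
      seed7 <- reverse_complement_rna(substr(mir, 2, 8))
      m8 <- substr(seed7, 1, 1)
      core6 <- substr(seed7, 2, 7)
      n_sites <- sample(1:2, 1, prob = c(0.7, 0.3))
      types <- sample(c("8mer", "7mer-m8", "7mer-A1"), n_sites, replace = TRUE)
      for (ty in types) {
        patch <- switch(ty,
          "8mer" = paste0(seed7, "A"),
          "7mer-m8" = paste0(seed7, sample(setdiff(bases, "A"), 1)),
          "7mer-A1" = paste0(sample(setdiff(bases, m8), 1), core6, "A"))
        # place away from ends and existing planted ranges
        for (try in 1:50) {
          pos <- sample(2:(utr_length - nchar(patch) - 1), 1)
          rng <- c(pos - 1, pos + nchar(patch))  # include one flank each side
          if (nrow(protected[[g]]) == 0 ||
              all(rng[2] < protected[[g]][, 1] | rng[1] > protected[[g]][, 2])) {
            substr(seqs[[g]], pos, pos + nchar(patch) - 1) <- patch
            protected[[g]] <- rbind(protected[[g]], rng)
            st <- switch(ty, "8mer" = pos, "7mer-m8" = pos, "7mer-A1" = pos + 1)
            en <- switch(ty, "8mer" = pos + 7, "7mer-m8" = pos + 6, "7mer-A1" = pos + 7)
            site_rows[[length(site_rows) + 1]] <- data.frame(
              gene_id = g, mature_id = target_pairs$mature_id[p],
              site_type = ty, utr_start = st, utr_end = en,
              stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
  }
  planted <- if (length(site_rows) > 0) do.call(rbind, site_rows) else
    data.frame(gene_id = character(), mature_id = character(),
               site_type = character(), utr_start = integer(),
               utr_end = integer())
  cores <- unique(vapply(names(mirna_seqs), function(m) {
    reverse_complement_rna(substr(mirna_seqs[[m]], 2, 7))
  }, character(1)))
  core_owner <- split(names(mirna_seqs),
                      vapply(names(mirna_seqs), function(m)
                        reverse_complement_rna(substr(mirna_seqs[[m]], 2, 7)),
                        character(1)))
  for (iter in 1:50) {
    dirty <- FALSE
    for (core in cores) {
      hits <- stringi::stri_locate_all_regex(seqs, paste0("(?=", core, ")"))
      for (gi in seq_along(seqs)) {
        starts <- hits[[gi]][, 1]
        if (length(starts) == 0 || is.na(starts[1])) next
        g <- names(seqs)[gi]
        own <- planted[planted$gene_id == g &
                         planted$mature_id %in% core_owner[[core]], , drop = FALSE]
        for (s in starts) {
          core_rng <- c(s, s + 5)
          legit <- nrow(own) > 0 &&
            any(core_rng[1] >= own$utr_start & core_rng[2] <= own$utr_end)
          if (legit) next
          prot <- protected[[g]]
          free <- setdiff(seq(core_rng[1], core_rng[2]),
                          unlist(apply(prot, 1, function(r) seq(r[1], r[2]),
                                       simplify = FALSE)))
          if (length(free) == 0) next  # fully inside another planted site
          pos <- free[(length(free) + 1) %/% 2]
          old <- substr(seqs[[gi]], pos, pos)
          substr(seqs[[gi]], pos, pos) <- sample(setdiff(bases, old), 1)
          dirty <- TRUE
        }
      }
    }
    if (!dirty) break
  }
  list(seqs = seqs, target_pairs = annotate_planted_pairs(target_pairs, planted),
       planted_sites = planted)
}

annotate_planted_pairs <- function(target_pairs, planted) {
  if (nrow(target_pairs) == 0) return(cbind(target_pairs, n_sites = integer(0),
                                            site_types = character(0)))
  key <- paste(planted$mature_id, planted$gene_id)
  target_pairs$n_sites <- vapply(
    paste(target_pairs$mature_id, target_pairs$gene_id),
    function(k) sum(key == k), integer(1))
  target_pairs$site_types <- vapply(
    paste(target_pairs$mature_id, target_pairs$gene_id),
    function(k) paste(sort(unique(planted$site_type[key == k])), collapse = ";"),
    character(1))
  rownames(target_pairs) <- NULL
  target_pairs
}

#' @export
print.mirflux_sim <- function(x, ...) {
  cat("mirflux synthetic dataset\n")
  cat(sprintf("  %d mature miRNAs, %d genes, %d tissue samples\n",
              nrow(x$tissue_counts$values),
              if (is.null(x$mrna)) 0 else nrow(x$mrna$values),
              ncol(x$tissue_counts$values)))
  cat(sprintf("  planted: %d age-DE miRNA-tissue effects, %d transport events, %d target pairs\n",
              nrow(x$truth$age_demirs), nrow(x$truth$transport_events),
              nrow(x$truth$target_pairs)))
  invisible(x)
}

#' Write a synthetic dataset to disk as pipeline-ready fixture files
#'
#' Emits every file the pipeline consumes (count TSVs with sample sheets,
#' long-format transcription map, FASTA for mature miRNAs and UTRs,
#' annotation, ageing-gene and category tables) plus truth TSVs for test
#' harnesses.
#'
#' @param sim A \code{mirflux_sim}.
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory. Default FALSE.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(sim, dir, force = FALSE) {
  stopifnot(inherits(sim, "mirflux_sim"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_expression_matrix(sim$tissue_counts, fp("tissue_counts.tsv"),
                          fp("tissue_samples.tsv"))
  write_expression_matrix(sim$umi_counts, fp("umi_counts.tsv"),
                          fp("umi_samples.tsv"))
  write_transcription_map(sim$tmap, fp("transcription_map.tsv"))
  write.table(sim$annotation, fp("mirna_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(sim$mirna_seqs, fp("mirna_mature.fa"))
  if (!is.null(sim$mrna)) {
    write_expression_matrix(sim$mrna, fp("mrna_expression.tsv"),
                            fp("mrna_samples.tsv"))
    write_fasta(sim$utr_seqs, fp("utr.fa"))
    writeLines(sim$genage, fp("genage.txt"))
    write.table(sim$wormcat, fp("wormcat.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  truth_dir <- fp("truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write.table(sim$truth$transport_events, file.path(truth_dir, "transport_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$age_demirs, file.path(truth_dir, "age_demirs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$sorting_weights, file.path(truth_dir, "sorting_weights.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$target_pairs, file.path(truth_dir, "target_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fixture directory back into a synthetic-dataset object
#'
#' @param dir Directory written by \code{\link{write_fixture}}.
#' @return A list with the same data slots as \code{\link{simulate_mirnaome}}
#'   (without the truth layer unless present on disk).
#' @export
read_fixture <- function(dir) {
  fp <- function(f) file.path(dir, f)
  out <- list(
    tissue_counts = read_expression_matrix(fp("tissue_counts.tsv"),
                                           fp("tissue_samples.tsv")),
    umi_counts = read_expression_matrix(fp("umi_counts.tsv"),
                                        fp("umi_samples.tsv")),
    tmap = read_transcription_map(fp("transcription_map.tsv")),
    annotation = read_mirna_annotation(fp("mirna_annotation.tsv")),
    mirna_seqs = read_fasta(fp("mirna_mature.fa")))
  if (file.exists(fp("mrna_expression.tsv"))) {
    out$mrna <- read_expression_matrix(fp("mrna_expression.tsv"),
                                       fp("mrna_samples.tsv"), scale = "tpm")
    out$utr_seqs <- read_fasta(fp("utr.fa"))
    out$genage <- readLines(fp("genage.txt"))
    out$wormcat <- read.delim(fp("wormcat.tsv"), stringsAsFactors = FALSE)
  }
  class(out) <- "mirflux_sim"
  out
}
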