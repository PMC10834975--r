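mir1 <- "UGGAAUGUAAAGAAGUAUGUAU"  # miR-1-3p

test_that("the miR-1 seed match is found as an 8mer and absent without complementarity", {
  utr <- paste0("GGGGGGGG", "ACAUUCCA", "GGGGGGGG")
  hits <- find_seed_sites(c(gene = utr), mir1)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$site_type, "8mer")
  expect_equal(hits$utr_start, 9)
  expect_equal(hits$utr_end, 16)
  # agrees with the independent sliding-window oracle
  orc <- oracle_seed_sites(utr, mir1)
  expect_equal(hits$utr_start, orc$utr_start)
  expect_identical(hits$site_type, orc$site_type)

  expect_equal(nrow(find_seed_sites(c(g = strrep("G", 40)), mir1)), 0)
  expect_error(find_seed_sites(c(g = "ACGTACGTT"), mir1), "alphabet")
})

test_that("all three site types are classified with 1-based inclusive spans", {
  seed7 <- "ACAUUCC"  # reverse complement of miR-1 positions 2-8
  utr <- paste0("GG", seed7, "G",      # 7mer-m8 at 3..9 (next base not A)
                "GG", "CAUUCCA",       # 7mer-A1 at 13..19 (prev base not m8)
                "GG", seed7, "A", "G") # 8mer at 22..29
  hits <- find_seed_sites(c(g = utr), mir1)
  hits <- hits[order(hits$utr_start), ]
  expect_identical(hits$site_type, c("7mer-m8", "7mer-A1", "8mer"))
  expect_equal(hits$utr_end - hits$utr_start + 1, c(7L, 7L, 8L))
  orc <- oracle_seed_sites(utr, mir1)
  expect_equal(hits$utr_start, orc$utr_start)
  expect_equal(hits$utr_end, orc$utr_end)
  expect_identical(hits$site_type, orc$site_type)
})

test_that("site finding equals the sliding-window oracle on random UTRs", {
  set.seed(70)
  mirnas <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""),
    character(1)), c("mA", "mB", "mC"))
  utrs <- setNames(vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "U"), 60, TRUE), collapse = ""),
    character(1)), sprintf("g%04d", 1:1000))
  for (m in names(mirnas)) {
    hits <- find_seed_sites(utrs, mirnas[[m]], mature_id = m)
    orc <- do.call(rbind, lapply(names(utrs), function(g) {
      o <- oracle_seed_sites(utrs[[g]], mirnas[[m]])
      if (nrow(o) > 0) cbind(gene_id = g, o)
    }))
    if (is.null(orc)) {
      expect_equal(nrow(hits), 0)
    } else {
      key_h <- sort(with(hits, paste(gene_id, utr_start, utr_end, site_type)))
      key_o <- sort(with(orc, paste(gene_id, utr_start, utr_end, site_type)))
      expect_identical(key_h, key_o)
    }
  }
})

test_that("anticorrelation is exact on linear constructions and random vectors", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(anticorrelation(x, -x + 10), -1, tolerance = 1e-12)
  expect_equal(anticorrelation(x, x), 1, tolerance = 1e-12)
  expect_error(anticorrelation(x, x[1:3]), "matched")
  cst <- anticorrelation(x, rep(2, 5))
  expect_true(is.na(cst))
  expect_identical(attr(cst, "reason"), "constant_vector")

  set.seed(71)
  a <- rnorm(20); b <- rnorm(20)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(anticorrelation(a, b), oracle, tolerance = 1e-12)
})

test_that("planted target pairs are recovered sensitively with low false discovery", {
  cfg <- generator_config(seed = 72)
  sim <- simulate_mirnaome(cfg)
  tpm <- compute_tpm(sim$tissue_counts)
  det <- call_detection_reads(sim$tissue_counts)
  mrna_det <- call_detection_reads(sim$mrna)
  pr <- te_profiles(det, sim$tmap, sim$annotation)
  pitt <- classify_pitt(pr)
  sites <- find_all_seed_sites(sim$utr_seqs, sim$mirna_seqs)
  res <- call_targets(tpm, sim$mrna, sites, det, mrna_det, pitt)

  truth_key <- with(sim$truth$target_pairs, paste(mature_id, gene_id))
  called_key <- with(res$pairs[res$pairs$passed, ], paste(mature_id, gene_id))
  sensitivity <- mean(truth_key %in% called_key)
  fdr <- if (length(called_key) > 0) mean(!(called_key %in% truth_key)) else 0
  expect_gte(sensitivity, 0.9)
  expect_lte(fdr, 0.2)

  # a pair needs both the site and the anti-correlation
  weak <- res$pairs[!res$pairs$passed & res$pairs$pcc > -0.2, ]
  if (nrow(weak) > 0) {
    expect_false(any(paste(weak$mature_id, weak$gene_id) %in% called_key))
  }
})

test_that("autonomy follows the PITT table and partitions every call", {
  cfg <- generator_config(seed = 73)
  sim <- simulate_mirnaome(cfg)
  tpm <- compute_tpm(sim$tissue_counts)
  det <- call_detection_reads(sim$tissue_counts)
  pr <- te_profiles(det, sim$tmap, sim$annotation)
  pitt <- classify_pitt(pr)
  sites <- find_all_seed_sites(sim$utr_seqs, sim$mirna_seqs)
  res <- call_targets(tpm, sim$mrna, sites, det,
                      call_detection_reads(sim$mrna), pitt)
  calls <- res$calls
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$autonomy %in% c("autonomous", "non_autonomous")))
  pitt_tab <- pitt$table
  pitt_key <- paste(pitt_tab$mature_id, pitt_tab$tissue,
                    pitt_tab$age)[pitt_tab$pitt]
  is_pitt <- with(calls, paste(mature_id, tissue, age)) %in% pitt_key
  expect_identical(calls$autonomy == "non_autonomous", is_pitt)
  # partition: per (tissue, age) the two classes sum to the total
  for (t in unique(calls$tissue)) for (a in unique(calls$age)) {
    sub <- calls[calls$tissue == t & calls$age == a, ]
    expect_equal(sum(sub$autonomy == "autonomous") +
                   sum(sub$autonomy == "non_autonomous"), nrow(sub))
  }
  # every call respects the correlation threshold and carries a site
  expect_true(all(calls$pcc < -0.2))
  expect_true(all(nzchar(calls$site_types)))
})
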