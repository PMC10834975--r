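make_umi_em <- function(w1, e1, w8 = w1, e8 = e1, ids = NULL) {
  # build a worm/EV UMI matrix whose replicate means equal the given vectors
  s <- make_samples(c("Worm", "EV"), reps = 3, unit = "UMI")
  n <- length(w1)
  if (is.null(ids)) ids <- sprintf("miR-%d", seq_len(n))
  v <- matrix(0, n, nrow(s), dimnames = list(ids, s$sample_id))
  fill <- function(tissue, age, vals) {
    v[, s$tissue == tissue & s$age == age] <<- matrix(rep(vals, 3), n)
  }
  fill("Worm", "D1", w1); fill("EV", "D1", e1)
  fill("Worm", "D8", w8); fill("EV", "D8", e8)
  make_em(v, s)
}

test_that("relative abundance is a proportion over the detected set", {
  em <- make_umi_em(w1 = c(40, 40, 2), e1 = c(30, 60, 2))
  det <- call_detection_umi(em, threshold = 10)
  rel <- relative_abundance(em, det)
  w <- rel[rel$compartment == "Worm" & rel$age == "D1", ]
  expect_equal(w$fraction, c(0.5, 0.5))           # equal means: 50/50
  expect_false("miR-3" %in% w$mature_id)          # undetected: dropped
  ev <- rel[rel$compartment == "EV" & rel$age == "D1", ]
  expect_equal(ev$fraction, c(1 / 3, 2 / 3))

  # conservation and the brute-force proportion oracle on random tensors
  set.seed(60)
  em2 <- random_counts_em(30, tissues = c("Worm", "EV"), unit = "UMI", lambda = 20)
  det2 <- call_detection_umi(em2)
  rel2 <- relative_abundance(em2, det2)
  for (comp in c("Worm", "EV")) for (a in c("D1", "D8")) {
    sub <- rel2[rel2$compartment == comp & rel2$age == a, ]
    expect_equal(sum(sub$fraction), 1, tolerance = 1e-12)
    idx <- which(em2$samples$tissue == comp & em2$samples$age == a)
    keep <- rowSums(em2$values[, idx]) >= 10
    means <- rowMeans(em2$values[keep, idx])
    expect_equal(setNames(sub$fraction, sub$mature_id),
                 means / sum(means), tolerance = 1e-12)
  }
})

test_that("loading ratios, the EV/worm symmetry and scale invariance hold", {
  em <- make_umi_em(w1 = c(40, 40), e1 = c(40, 40))
  det <- call_detection_umi(em)
  lr <- loading_ratio(relative_abundance(em, det))
  expect_equal(lr$ratio_d1, c(1, 1))
  expect_equal(lr$ratio_d8, c(1, 1))
  cls <- classify_secretion(lr)
  expect_true(all(cls$table$secretion_class == "stable"))

  # asymmetric case: swapping compartments inverts the ratio and classes
  em2 <- make_umi_em(w1 = c(40, 40), e1 = c(70, 10),
                     w8 = c(40, 40), e8 = c(10, 70))
  det2 <- call_detection_umi(em2)
  lr2 <- loading_ratio(relative_abundance(em2, det2))
  em_sw <- em2
  em_sw$samples$tissue <- ifelse(em2$samples$tissue == "Worm", "EV", "Worm")
  det_sw <- call_detection_umi(em_sw)
  lr_sw <- loading_ratio(relative_abundance(em_sw, det_sw))
  expect_equal(lr_sw$ratio_d1, 1 / lr2$ratio_d1, tolerance = 1e-12)
  expect_equal(lr_sw$age_change, 1 / lr2$age_change, tolerance = 1e-12)
  c2 <- classify_secretion(lr2)$table$secretion_class
  c_sw <- classify_secretion(lr_sw)$table$secretion_class
  expect_identical(c_sw[c2 == "promoted"], rep("suppressed", sum(c2 == "promoted")))
  expect_identical(c_sw[c2 == "suppressed"], rep("promoted", sum(c2 == "suppressed")))

  # multiplying one compartment-age by a constant changes nothing
  em3 <- em2
  scale_idx <- em3$samples$tissue == "EV" & em3$samples$age == "D1"
  em3$values[, scale_idx] <- em3$values[, scale_idx] * 17
  lr3 <- loading_ratio(relative_abundance(em3, call_detection_umi(em3)))
  expect_equal(lr3$ratio_d1, lr2$ratio_d1, tolerance = 1e-12)
  expect_equal(lr3$age_change, lr2$age_change, tolerance = 1e-12)
})

test_that("secretion classes use strict two-fold bounds", {
  tab <- data.frame(mature_id = c("a", "b", "c", "d"),
                    age_change = c(2, 0.4, 2.01, NA))
  cls <- classify_secretion(tab)
  expect_identical(cls$table$secretion_class,
                   c("stable", "suppressed", "promoted", "undetermined"))
  expect_equal(unname(cls$counts), c(1L, 1L, 1L, 1L))

  # counts match a brute-force threshold sweep
  set.seed(61)
  tab2 <- data.frame(mature_id = sprintf("m%d", 1:50),
                     age_change = rlnorm(50, 0, 1))
  for (thr in c(1.5, 2, 3)) {
    cls2 <- classify_secretion(tab2, thr)
    expect_equal(unname(cls2$counts["promoted"]), sum(tab2$age_change > thr))
    expect_equal(unname(cls2$counts["suppressed"]), sum(tab2$age_change < 1 / thr))
  }
})

test_that("miRNAs missing one side are undetermined with a reason", {
  em <- make_umi_em(w1 = c(40, 40), e1 = c(40, 1), e8 = c(40, 1))
  det <- call_detection_umi(em)
  lr <- loading_ratio(relative_abundance(em, det))
  r2 <- lr[lr$mature_id == "miR-2", ]
  expect_true(is.na(r2$age_change))
  expect_identical(r2$reason, "missing_both_ages")
  expect_identical(
    classify_secretion(lr)$table$secretion_class[lr$mature_id == "miR-2"],
    "undetermined")
})

test_that("recovered secretion classes match the planted realized classes", {
  conc <- vapply(1:5, function(i) {
    sim <- simulate_mirnaome(generator_config(seed = 7000 + i))
    lr <- loading_ratio(relative_abundance(sim$umi_counts,
                                           call_detection_umi(sim$umi_counts)))
    cls <- classify_secretion(lr)$table
    w <- sim$truth$sorting_weights
    m <- merge(cls[, c("mature_id", "secretion_class")],
               w[, c("mature_id", "secretion_class")],
               by = "mature_id", suffixes = c("_rec", "_truth"))
    ok <- m$secretion_class_rec != "undetermined"
    mean(m$secretion_class_rec[ok] == m$secretion_class_truth[ok])
  }, numeric(1))
  expect_gte(mean(conc), 0.85)
})
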