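test_that("TPM equals per-column proportions times one million", {
  s <- make_samples("Neu", reps = 1)
  v <- matrix(c(10, 30, 60, 1, 1, 2), 3, 2)
  em <- make_em(v, s[1:2, ])
  tpm <- compute_tpm(em)
  expect_equal(tpm$values[, 1], c(1e5, 3e5, 6e5), ignore_attr = TRUE)
  expect_equal(unname(colSums(tpm$values)), rep(1e6, 2))
  expect_identical(tpm$scale, "tpm")

  set.seed(10)
  em2 <- random_counts_em(50, tissues = c("Neu", "Int"))
  tpm2 <- compute_tpm(em2)
  # independent oracle: explicit per-column proportion loop
  oracle <- em2$values
  for (j in seq_len(ncol(oracle))) oracle[, j] <- em2$values[, j] / sum(em2$values[, j]) * 1e6
  expect_equal(tpm2$values, oracle, tolerance = 1e-12)
  expect_equal(unname(colSums(tpm2$values)), rep(1e6, ncol(oracle)), tolerance = 1e-6)

  em_zero <- em
  em_zero$values[, 2] <- 0
  expect_error(compute_tpm(em_zero), "Neu_D8_r1")
})

test_that("quantile normalization matches the row-mean reference and is idempotent", {
  set.seed(11)
  v <- matrix(rlnorm(200, 5, 2), 40, 5)
  q <- quantile_normalize(v)
  # columns share one sorted multiset: the mean of sorted columns
  ref <- rowMeans(apply(v, 2, sort))
  for (j in 1:5) expect_equal(sort(q[, j]), ref, tolerance = 1e-12)
  # within-column order preserved
  for (j in 1:5) expect_equal(order(q[, j]), order(v[, j]))
  expect_equal(quantile_normalize(q), q, tolerance = 1e-12)

  # permuted columns become identical after normalization
  v2 <- cbind(v[, 1], sample(v[, 1]))
  q2 <- quantile_normalize(v2)
  expect_equal(sort(q2[, 1]), sort(q2[, 2]), tolerance = 1e-12)

  # cross-check against limma on a tie-free matrix
  skip_if_not_installed("limma")
  expect_equal(q, unname(limma::normalizeQuantiles(v)), tolerance = 1e-10)
})

test_that("tied values receive the mean of the implicated reference quantiles", {
  v <- cbind(c(1, 1, 5, 9), c(2, 4, 6, 8))
  q <- quantile_normalize(v)
  ref <- rowMeans(apply(v, 2, sort))
  expect_equal(q[1:2, 1], rep(mean(ref[1:2]), 2))
  expect_equal(q[3:4, 1], ref[3:4])
})

test_that("log2 quantile normalization enforces its input contract", {
  s <- make_samples("Neu", reps = 1)[1:2, ]
  em <- make_em(matrix(c(10, 30, 60, 20, 20, 60), 3, 2), s)
  expect_error(log2_quantile_normalize(em), "TPM")
  tpm <- compute_tpm(em)
  qn <- log2_quantile_normalize(tpm)
  expect_identical(qn$scale, "qnorm_log2tpm")
  # single column: plain log2(tpm + pseudocount)
  em1 <- make_em(matrix(c(10, 30, 60), 3, 1), s[1, , drop = FALSE])
  qn1 <- log2_quantile_normalize(compute_tpm(em1))
  expect_equal(qn1$values[, 1], log2(compute_tpm(em1)$values[, 1] + 1),
               ignore_attr = TRUE)
})

test_that("read detection uses a strict threshold and the configured group rule", {
  s <- make_samples("BWM", ages = "D1", reps = 3)
  em <- make_em(matrix(c(6, 6, 6, 5, 5, 5, 0, 9, 9), 3, 3, byrow = TRUE), s)
  det <- call_detection_reads(em, threshold = 5)
  expect_true(det$per_group[1, "BWM", "D1"])    # (6,6,6): mean 6 > 5
  expect_false(det$per_group[2, "BWM", "D1"])   # (5,5,5): strict inequality
  expect_true(det$per_group[3, "BWM", "D1"])    # mean 6 > 5 under mean rule
  det_all <- call_detection_reads(em, threshold = 5, group_rule = "all")
  expect_false(det_all$per_group[3, "BWM", "D1"])
  det_any <- call_detection_reads(em, threshold = 5, group_rule = "any")
  expect_true(det_any$per_group[3, "BWM", "D1"])

  set.seed(12)
  em2 <- random_counts_em(30, lambda = 6)
  for (rule in c("mean", "any", "all")) {
    det2 <- call_detection_reads(em2, group_rule = rule)
    for (t in five_tissues) for (a in c("D1", "D8")) {
      idx <- which(em2$samples$tissue == t & em2$samples$age == a)
      for (m in 1:30) {
        cnt <- em2$values[m, idx]
        want <- switch(rule, mean = mean(cnt) > 5, any = any(cnt > 5),
                       all = all(cnt > 5))
        expect_identical(unname(det2$per_group[m, t, a]), want)
      }
    }
  }
})

test_that("detection is monotone: raising a count never loses a call", {
  set.seed(13)
  em <- random_counts_em(20, tissues = "Hyp", lambda = 6)
  det <- call_detection_reads(em)
  em_up <- em
  em_up$values <- em$values + matrix(rpois(length(em$values), 2),
                                     nrow(em$values))
  det_up <- call_detection_reads(em_up)
  expect_true(all(det_up$per_group[det$per_group]))
  expect_true(all(det_up$per_replicate[det$per_replicate]))
})

test_that("UMI detection sums replicates with an inclusive threshold", {
  s <- make_samples(c("Worm", "EV"), reps = 3, unit = "UMI")
  v <- matrix(0, 2, nrow(s), dimnames = list(c("m1", "m2"), s$sample_id))
  v["m1", s$tissue == "Worm" & s$age == "D1"] <- c(3, 3, 4)   # sum 10
  v["m2", s$tissue == "Worm" & s$age == "D1"] <- c(9, 0, 0)   # sum 9
  em <- make_em(v, s)
  det <- call_detection_umi(em, threshold = 10)
  expect_true(det$per_group["m1", "Worm", "D1"])
  expect_false(det$per_group["m2", "Worm", "D1"])

  set.seed(14)
  em2 <- random_counts_em(40, tissues = c("Worm", "EV"), unit = "UMI", lambda = 4)
  det2 <- call_detection_umi(em2)
  for (t in c("Worm", "EV")) for (a in c("D1", "D8")) {
    idx <- which(em2$samples$tissue == t & em2$samples$age == a)
    expect_identical(unname(det2$per_group[, t, a]),
                     unname(rowSums(em2$values[, idx]) >= 10))
  }
  expect_error(call_detection_umi(random_counts_em(5, tissues = "Worm")),
               "UMI")
})

test_that("ordination recovers duplicate and group structure", {
  set.seed(15)
  s <- make_samples(c("Neu", "Int"), ages = "D1", reps = 2)
  base <- rlnorm(60, 4, 1)
  v <- cbind(base, base, base + rnorm(60, 8), base + rnorm(60, 8))
  em <- make_em(v, s, scale = "raw_count")
  em$scale <- "qnorm_log2tpm"
  qc <- ordination_qc(em)
  # duplicated columns: perfect correlation, coincident PCA coordinates
  expect_equal(qc$pearson[1, 2], 1, tolerance = 1e-12)
  expect_equal(qc$pca$PC1[1], qc$pca$PC1[2], tolerance = 1e-8)
  # first PC separates the two constructed groups
  expect_true(all(sign(qc$pca$PC1[1:2]) != sign(qc$pca$PC1[3:4])))

  # Pearson matrix equals the brute-force covariance formula
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    a <- v[, i]; b <- v[, j]
    oracle[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(unname(qc$pearson), oracle, tolerance = 1e-10)

  v2 <- v; v2[, 4] <- 7
  em2 <- make_em(v2, s, scale = "raw_count")
  expect_warning(qc2 <- ordination_qc(em2), "constant")
  expect_equal(qc2$excluded, s$sample_id[4])
})
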