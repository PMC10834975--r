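test_that("a muscle-transcribed miRNA detected everywhere is PITT outside muscle", {
  pr <- profiles_from_membership(
    sources = list("BWM"),
    receivers = list(c("Neu", "Int", "Hyp", "Coel")))
  pitt <- classify_pitt(pr)
  expect_identical(pitt$pitt, "miR-1")
  tab <- pitt$table
  expect_setequal(tab$tissue[tab$pitt], c("Neu", "Int", "Hyp", "Coel"))
  expect_false(tab$pitt[tab$tissue == "BWM"])

  # transcribed in every tissue: never PITT regardless of expression
  pr2 <- profiles_from_membership(sources = list(five_tissues),
                                  receivers = list(character(0)))
  expect_length(classify_pitt(pr2)$pitt, 0)
})

test_that("PITT classification equals the brute-force double loop on random tensors", {
  set.seed(40)
  for (rep in 1:5) {
    m <- 15
    ids <- sprintf("miR-%d", 1:m)
    E <- array(runif(m * 5 * 2) < 0.5, dim = c(m, 5, 2),
               dimnames = list(ids, five_tissues, c("D1", "D8")))
    T_ <- array(runif(m * 5 * 2) < 0.4, dim = dim(E), dimnames = dimnames(E))
    pr <- list(E = E, T_ = T_, tissues = five_tissues, ages = c("D1", "D8"))
    pitt <- classify_pitt(pr)
    oracle <- character(0)
    for (i in ids) for (t in five_tissues) for (a in c("D1", "D8")) {
      if (E[i, t, a] && !T_[i, t, a]) oracle <- c(oracle, i)
    }
    expect_setequal(pitt$pitt, unique(oracle))
  }
})

test_that("PITT calls are monotone in T and E", {
  set.seed(41)
  m <- 12
  ids <- sprintf("miR-%d", 1:m)
  E <- array(runif(m * 10) < 0.5, dim = c(m, 5, 2),
             dimnames = list(ids, five_tissues, c("D1", "D8")))
  T_ <- array(runif(m * 10) < 0.3, dim = dim(E), dimnames = dimnames(E))
  pr <- list(E = E, T_ = T_, tissues = five_tissues, ages = c("D1", "D8"))
  base <- classify_pitt(pr)$pitt
  T2 <- T_; T2[sample(which(!T_), 5)] <- TRUE   # add transcription calls
  expect_true(all(classify_pitt(list(E = E, T_ = T2, tissues = five_tissues,
                                     ages = c("D1", "D8")))$pitt %in% base))
  E2 <- E; E2[sample(which(!E), 5)] <- TRUE     # add expression calls
  expect_true(all(base %in% classify_pitt(list(E = E2, T_ = T_,
                                               tissues = five_tissues,
                                               ages = c("D1", "D8")))$pitt))
})

test_that("network edges follow the source x receiver product rule", {
  pr <- profiles_from_membership(
    sources = list("BWM", c("Neu", "Int"), character(0)),
    receivers = list("Int", c("BWM", "Coel"), c("Hyp", "Neu")))
  net <- build_trafficking_network(pr, "D1")
  e <- net$edges
  get_w <- function(s, t) e$weight[e$source == s & e$target == t]
  expect_equal(get_w("BWM", "Int"), 1)
  # multi-source miRNA contributes to all four source x receiver edges
  for (s in c("Neu", "Int")) for (t in c("BWM", "Coel")) {
    expect_gte(get_w(s, t), 1)
  }
  # sourceless miRNA flows from Other into each receiver
  expect_equal(get_w("Other", "Hyp"), 1)
  expect_equal(get_w("Other", "Neu"), 1)
  expect_true(all(e$source != e$target))
  # total memberships: |S| x |R| per miRNA (|R| for Other-source)
  expect_equal(sum(e$weight), 1 * 1 + 2 * 2 + 2)
  # weight always equals the length of the miRNA list
  n_listed <- vapply(strsplit(e$mirnas, ";"), function(x)
    sum(nzchar(x)), integer(1))
  expect_equal(e$weight, n_listed)
})

test_that("consistent tissue relabeling permutes the network equivariantly", {
  set.seed(42)
  mb <- random_membership(20)
  pr <- profiles_from_membership(mb$sources, mb$receivers)
  net <- build_trafficking_network(pr, "D1")
  perm <- setNames(sample(five_tissues), five_tissues)
  relabel <- function(x) unname(perm[x])
  pr2 <- profiles_from_membership(lapply(mb$sources, relabel),
                                  lapply(mb$receivers, relabel))
  # keep tissue order fixed; only the labels of the calls moved
  net2 <- build_trafficking_network(pr2, "D1")
  e1 <- net$edges; e2 <- net2$edges
  for (i in seq_len(nrow(e1))) {
    s2 <- if (e1$source[i] == "Other") "Other" else unname(perm[e1$source[i]])
    w2 <- e2$weight[e2$source == s2 & e2$target == unname(perm[e1$target[i]])]
    expect_equal(w2, e1$weight[i])
  }
})

test_that("noiseless generator is recovered exactly: PITT set and planted edges", {
  cfg <- generator_config(n_mirnas = 40, n_genes = 0, n_target_pairs = 0,
                          noiseless = TRUE, seed = 43)
  sim <- simulate_mirnaome(cfg)
  det <- call_detection_reads(sim$tissue_counts)
  pr <- te_profiles(det, sim$tmap, sim$annotation)
  pitt <- classify_pitt(pr)
  transported <- unique(sim$truth$transport_events$mature_id)
  expect_setequal(pitt$pitt, transported)

  for (a in c("D1", "D8")) {
    net <- build_trafficking_network(pr, a)
    ev <- sim$truth$transport_events[sim$truth$transport_events$age == a, ]
    for (k in seq_len(nrow(ev))) {
      srcs <- strsplit(ev$sources[k], ";")[[1]]
      recs <- strsplit(ev$receivers[k], ";")[[1]]
      for (s in srcs) for (r in recs) {
        row <- net$edges[net$edges$source == s & net$edges$target == r, ]
        expect_true(grepl(ev$mature_id[k], row$mirnas, fixed = TRUE))
      }
    }
    # single-source events: the reconstructed membership matches exactly
    single <- ev[!grepl(";", ev$sources), ]
    for (k in seq_len(nrow(single))) {
      mb <- net$membership[[single$mature_id[k]]]
      expect_identical(sort(mb$sources), sort(strsplit(single$sources[k], ";")[[1]]))
      expect_identical(sort(mb$receivers), sort(strsplit(single$receivers[k], ";")[[1]]))
    }
  }
})

test_that("flow summary counts distinct transported miRNAs per role", {
  s <- make_samples(five_tissues)
  v <- matrix(0, 3, nrow(s), dimnames = list(paste0("miR-", 1:3), s$sample_id))
  # three miRNAs transcribed in BWM, detected in BWM and Int in every sample
  v[, s$tissue %in% c("BWM", "Int")] <- 50
  em <- make_em(v, s)
  ann <- data.frame(mature_id = paste0("miR-", 1:3),
                    gene_id = paste0("mir-", 1:3), stringsAsFactors = FALSE)
  calls <- array(FALSE, dim = c(3, 5, 2),
                 dimnames = list(ann$gene_id, five_tissues, c("D1", "D8")))
  calls[, "BWM", ] <- TRUE
  fl <- flow_summary(em, transcription_map(calls), ann)
  expect_equal(nrow(fl), 5 * 2 * 3)  # tissue x age x replicate
  expect_true(all(fl$n_out[fl$tissue == "BWM"] == 3))
  expect_true(all(fl$n_in[fl$tissue == "Int"] == 3))
  expect_true(all(fl$n_out[fl$tissue != "BWM"] == 0))
  expect_true(all(fl$n_in[fl$tissue != "Int"] == 0))
})

test_that("flow summary equals a brute-force recount from per-replicate calls", {
  cfg <- generator_config(n_mirnas = 25, n_genes = 0, n_target_pairs = 0, seed = 44)
  sim <- simulate_mirnaome(cfg)
  fl <- flow_summary(sim$tissue_counts, sim$tmap, sim$annotation)
  gene_of <- setNames(sim$annotation$gene_id, sim$annotation$mature_id)
  for (pick in sample(nrow(fl), 10)) {
    t0 <- fl$tissue[pick]; a0 <- fl$age[pick]; r0 <- fl$replicate[pick]
    n_out <- 0; n_in <- 0
    for (m in rownames(sim$tissue_counts$values)) {
      E <- vapply(five_tissues, function(t) {
        j <- which(sim$tissue_counts$samples$tissue == t &
                   sim$tissue_counts$samples$age == a0 &
                   sim$tissue_counts$samples$replicate == r0)
        sim$tissue_counts$values[m, j] > 5
      }, logical(1))
      T_ <- sim$tmap$calls[gene_of[m], five_tissues, a0]
      S <- five_tissues[E & T_]; R <- five_tissues[E & !T_]
      if (t0 %in% S && length(R) > 0) n_out <- n_out + 1
      if (t0 %in% R) n_in <- n_in + 1
    }
    expect_equal(fl$n_out[pick], n_out)
    expect_equal(fl$n_in[pick], n_in)
  }
})
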