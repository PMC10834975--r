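# shared fixture builders; all randomness is seeded by the caller

five_tissues <- c("Neu", "Int", "BWM", "Hyp", "Coel")

make_samples <- function(tissues, ages = c("D1", "D8"), reps = 3,
                         unit = "reads") {
  s <- expand.grid(replicate = seq_len(reps), age = ages, tissue = tissues,
                   stringsAsFactors = FALSE)[, c("tissue", "age", "replicate")]
  s$sample_id <- sprintf("%s_%s_r%d", s$tissue, s$age, s$replicate)
  s$count_unit <- unit
  s
}

make_em <- function(values, samples, scale = "raw_count") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("miR-%d", seq_len(nrow(values)))
  }
  if (ncol(values) == nrow(samples)) colnames(values) <- samples$sample_id
  expression_matrix(values, samples, scale = scale)
}

random_counts_em <- function(n_feat, tissues = five_tissues, reps = 3,
                             unit = "reads", lambda = 50) {
  s <- make_samples(tissues, reps = reps, unit = unit)
  v <- matrix(rpois(n_feat * nrow(s), lambda), n_feat, nrow(s))
  make_em(v, s)
}

# build T/E profile arrays directly from per-miRNA source/receiver sets,
# bypassing count simulation (used for network null calibration)
profiles_from_membership <- function(sources, receivers, tissues = five_tissues,
                                     age = "D1") {
  m <- length(sources)
  ids <- sprintf("miR-%d", seq_len(m))
  E <- array(FALSE, dim = c(m, length(tissues), 1),
             dimnames = list(ids, tissues, age))
  T_ <- E
  for (i in seq_len(m)) {
    E[i, c(sources[[i]], receivers[[i]]), 1] <- TRUE
    T_[i, sources[[i]], 1] <- TRUE
  }
  list(E = E, T_ = T_, tissues = tissues, ages = age)
}

random_membership <- function(n, tissues = five_tissues) {
  sources <- vector("list", n); receivers <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    r <- sample(1:2, 1)
    perm <- sample(tissues, s + r)
    sources[[i]] <- perm[seq_len(s)]
    receivers[[i]] <- perm[s + seq_len(r)]
  }
  list(sources = sources, receivers = receivers)
}

# independent sliding-window seed-site oracle (no shared code with the
# package matcher): enumerate every window and compare against the literal
# site strings
oracle_seed_sites <- function(utr, mirna) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  seed7 <- rc(substr(mirna, 2, 8))
  core6 <- rc(substr(mirna, 2, 7))
  site8 <- paste0(seed7, "A")
  hits <- list()
  n <- nchar(utr)
  for (i in seq_len(n)) {
    w8 <- substr(utr, i, i + 7)
    w7 <- substr(utr, i, i + 6)
    if (nchar(w8) == 8 && w8 == site8) {
      hits[[length(hits) + 1]] <- c(i, i + 7, "8mer")
    } else if (nchar(w7) == 7 && w7 == seed7 &&
               substr(utr, i + 7, i + 7) != "A") {
      hits[[length(hits) + 1]] <- c(i, i + 6, "7mer-m8")
    } else if (nchar(w7) == 7 && w7 == paste0(core6, "A") &&
               (i == 1 || substr(utr, i - 1, i - 1) != substr(seed7, 1, 1))) {
      hits[[length(hits) + 1]] <- c(i, i + 6, "7mer-A1")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(utr_start = integer(), utr_end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, hits)
  data.frame(utr_start = as.integer(m[, 1]), utr_end = as.integer(m[, 2]),
             site_type = m[, 3], stringsAsFactors = FALSE)
}
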