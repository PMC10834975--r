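#!/usr/bin/env Rscript
# One-shot orchestration: run every stage through run_all() on the fixture
# and emit the complete report bundle, including the cascade counts that
# summarize the whole analysis.

library(mirflux)

fx <- read_fixture("results/analysis/fixture")
res <- run_all(fx, analysis_config(n_permutations = 1000, rng_seed = 42))
write_report(res, "results/analysis/report")

cat("cascade counts:\n")
for (nm in names(res$counts)) {
  v <- res$counts[[nm]]
  cat(sprintf("  %-32s %s\n", nm,
              if (is.numeric(v)) format(round(v, 1)) else format(v)))
}
cat("report written to results/analysis/report\n")
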