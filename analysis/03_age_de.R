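#!/usr/bin/env Rscript
# Age differential expression per tissue: Box-Cox transform then two-sided
# pooled t-test (p < 0.05) on every miRNA expressed at D1 or D8, yielding
# the Age-DEMIR sets, their cross-tissue overlap and shared-set decay.

library(mirflux)

fx <- read_fixture("results/analysis/fixture")
out <- "results/analysis"

tpm <- compute_tpm(fx$tissue_counts)
det <- call_detection_reads(fx$tissue_counts)
de <- call_age_demirs(tpm, det)

write.table(de$results, file.path(out, "age_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

per_tissue <- lapply(de$demirs$per_tissue, function(s) c(s$up, s$down))
ov <- overlap_report(per_tissue)
decay <- shared_set_decay(per_tissue)
write.table(ov, file.path(out, "age_demir_overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(decay, file.path(out, "age_demir_shared_decay.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Age-DEMIRs (union over tissues):", length(de$demirs$union), "\n")
for (t in names(per_tissue)) {
  tested <- sum(de$results$tissue == t)
  cat(sprintf("  %-5s %2d / %2d tested (%.1f%%)\n", t,
              length(per_tissue[[t]]), tested,
              100 * length(per_tissue[[t]]) / tested))
}
cat("shared Age-DEMIRs by >=k tissues:",
    paste(decay$n_shared, collapse = " "), "\n")

# against planted truth
truth <- read.delim("results/analysis/fixture/truth/age_demirs.tsv")
key <- paste(de$results$mature_id, de$results$tissue)
hit <- mapply(function(m, t, d) {
  r <- match(paste(m, t), key)
  !is.na(r) && de$results$significant[r] && de$results$direction[r] == d
}, truth$mature_id, truth$tissue, truth$direction)
cat(sprintf("recall of planted effects: %.2f (%d/%d)\n",
            mean(hit), sum(hit), length(hit)))
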