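#!/usr/bin/env Rscript
# Normalize the tissue miRNA counts (TPM, then quantile-normalized log2),
# call expression per replicate and per (tissue, age) group under the
# more-than-five-reads rule, and run ordination QC.

library(mirflux)

fx <- read_fixture("results/analysis/fixture")
out <- "results/analysis"

tpm <- compute_tpm(fx$tissue_counts)
qn <- log2_quantile_normalize(tpm)
det <- call_detection_reads(fx$tissue_counts)

write_expression_matrix(tpm, file.path(out, "tpm.tsv"))
write_expression_matrix(qn, file.path(out, "qnorm_log2tpm.tsv"))
write.table(detection_long(det), file.path(out, "detection_group.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

qc <- ordination_qc(qn)
write.table(qc$pca[, 1:8], file.path(out, "pca.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(round(qc$pearson, 6), file.path(out, "sample_correlation.tsv"),
            sep = "\t", quote = FALSE)

n_detected <- sum(apply(det$per_group, 1, any, na.rm = TRUE))
cat("matures detected in >=1 tissue-age group:", n_detected, "of",
    nrow(fx$tissue_counts$values), "\n")
cat("variance explained by PC1/PC2:",
    round(100 * qc$var_explained[1:2], 1), "%\n")
# replicates of one tissue-age should be each other's nearest neighbours
same_group <- outer(paste(qn$samples$tissue, qn$samples$age),
                    paste(qn$samples$tissue, qn$samples$age), "==")
diag(same_group) <- NA
r_within <- mean(qc$pearson[which(same_group)])
r_between <- mean(qc$pearson[which(!same_group)])
cat(sprintf("mean Pearson r within groups %.3f vs between groups %.3f\n",
            r_within, r_between))
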