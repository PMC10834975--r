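#!/usr/bin/env Rscript
# Worm vs EV miRNAome: UMI detection (sum >= 10 over 3 replicates),
# age differential expression in each compartment (p < 0.05 and FC > 1.5),
# relative abundance, EV loading ratios and selective-secretion classes.

library(mirflux)

fx <- read_fixture("results/analysis/fixture")
out <- "results/analysis"

udet <- call_detection_umi(fx$umi_counts)
rel <- relative_abundance(fx$umi_counts, udet)
lr <- loading_ratio(rel)
secr <- classify_secretion(lr)
write.table(secr$table, file.path(out, "ev_loading.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ev_de <- call_age_demirs(compute_tpm(fx$umi_counts), udet, mode = "compartment")
write.table(ev_de$results, file.path(out, "ev_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_ev <- sum(udet$per_group[, "EV", "D1"] | udet$per_group[, "EV", "D8"])
n_worm <- sum(udet$per_group[, "Worm", "D1"] | udet$per_group[, "Worm", "D8"])
cat("detected miRNAs: EV", n_ev, "/ worm", n_worm, "\n")
ev_rows <- ev_de$results[ev_de$results$tissue == "EV", ]
cat("EV age-DE:", sum(ev_rows$direction == "up"), "up /",
    sum(ev_rows$direction == "down"), "down\n")
cat("secretion classes:", paste(names(secr$counts), secr$counts,
                                collapse = ", "), "\n")

# planted sorting weights vs recovered loading ratios
w <- read.delim("results/analysis/fixture/truth/sorting_weights.tsv")
ok <- !is.na(lr$ratio_d1)
sp <- cor(lr$ratio_d1[ok], w$weight_d1[match(lr$mature_id[ok], w$mature_id)],
          method = "spearman")
cat(sprintf("Spearman of D1 loading ratio vs planted sorting weight: %.3f (n = %d)\n",
            sp, sum(ok)))
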