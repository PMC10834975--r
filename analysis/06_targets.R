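#!/usr/bin/env Rscript
# Target inference: canonical seed sites in the 3'UTRs plus Pearson
# anti-correlation (< -0.2) across tissue x age condition means; calls are
# partitioned into autonomous and non-autonomous (PITT-driven) per tissue
# and age, annotated with ageing genes and category enrichment.

library(mirflux)

fx <- read_fixture("results/analysis/fixture")
out <- "results/analysis"

tpm <- compute_tpm(fx$tissue_counts)
det <- call_detection_reads(fx$tissue_counts)
mdet <- call_detection_reads(fx$mrna)
pitt <- classify_pitt(te_profiles(det, fx$tmap, fx$annotation))
sites <- find_all_seed_sites(fx$utr_seqs, fx$mirna_seqs)
tg <- call_targets(tpm, fx$mrna, sites, det, mdet, pitt)

write.table(sites, file.path(out, "seed_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tg$pairs, file.path(out, "target_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tg$calls, file.path(out, "target_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("candidate pairs with >=1 seed site:", nrow(tg$pairs), "\n")
cat("pairs passing anti-correlation:", sum(tg$pairs$passed), "\n")
cat("target calls (pair x tissue x age):", nrow(tg$calls), "\n")
frac_na <- mean(tg$calls$autonomy == "non_autonomous")
cat(sprintf("non-autonomous fraction of calls: %.1f%%\n", 100 * frac_na))

gf <- genage_fraction(unique(tg$calls$gene_id), fx$genage)
cat(sprintf("ageing-annotated fraction of target genes: %.1f%% (%d/%d)\n",
            100 * gf$fraction, gf$n_annotated, gf$n_targets))

background <- rownames(fx$mrna$values)[apply(mdet$per_group, 1, any, na.rm = TRUE)]
enr <- category_enrichment(intersect(unique(tg$calls$gene_id), background),
                           background, fx$wormcat)
write.table(enr, file.path(out, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- enr[enr$level == "Category1" & enr$p < 0.05, ]
cat("enriched Category1 terms (p < 0.05):",
    if (nrow(top)) paste(top$category, collapse = ", ") else "none", "\n")
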