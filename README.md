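# mirflux

Tissue-resolved analysis of miRNA ageing and inter-tissue miRNA
trafficking in *Caenorhabditis elegans*.

Ageing changes gene regulation differently in different tissues, and
miRNAs are both local regulators and intercellular messengers carried
between tissues by extracellular vesicles (EVs). Given small-RNA count
matrices from five isolated somatic tissues (neurons, intestine, body wall
muscle, hypodermis, coelomocytes) at day 1 and day 8 of adulthood,
promoter-reporter transcription maps, whole-worm and EV UMI libraries, and
matched mRNA expression, mirflux answers, stage by stage:

1. **Age-DEMIRs** — which miRNAs change with age in which tissue. Per
   miRNA and tissue, pooled D1+D8 values are Box-Cox transformed
   (λ by maximum likelihood) and compared by a two-sided pooled-variance
   t-test; tissue calls use *p* < 0.05, compartment (worm/EV) calls
   additionally require FC > 1.5 or < 1/1.5.
2. **PITT-miRs** — miRNAs detected by sequencing (E: more than 5 reads) in
   a tissue without promoter activity there (T): E ∧ ¬T flags potential
   inter-tissue transport.
3. **Trafficking network** — each miRNA joins every directed edge from its
   source tissues (E ∧ T) to its receiver tissues (E ∧ ¬T). Edge weights
   are tested against a degree-preserving permutation null (1000
   redraws); null samples are Yeo-Johnson transformed and
   z = (w′obs − mean)/sd gives two-sided normal p-values.
4. **EV loading** — relative abundance among detected miRNAs per
   compartment and age; the loading ratio (EV share / worm share) and its
   D8/D1 change classify secretion as promoted (> 2-fold), suppressed
   (< 1/2) or stable.
5. **Targets and autonomy** — canonical seed sites (8mer, 7mer-m8,
   7mer-A1) in 3′UTRs plus Pearson anti-correlation < −0.2 across the ten
   tissue × age mean profiles define targets; calls are non-autonomous
   where the miRNA is PITT in that tissue and age. Target sets are
   annotated against an ageing-gene list and tested for category
   enrichment (one-sided Fisher).

A synthetic-data generator (`simulate_mirnaome()`) produces the complete
data bundle with planted truth — transcription maps, transport events, age
effects, EV sorting weights, seeded UTRs — so every stage is testable
without downloads. See `vignettes/tissue-mirna-ageing.Rmd` for the methods
account.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run the
scripts in order from the repository root:

```sh
Rscript analysis/01_simulate.R        # synthetic study + fixture
Rscript analysis/02_normalize_detect.R
Rscript analysis/03_age_de.R
Rscript analysis/04_pitt_network.R
Rscript analysis/05_ev_sorting.R
Rscript analysis/06_targets.R
Rscript analysis/07_report.R          # everything again via run_all()
```

`03_age_de.R` prints, for the default seed:

```
Age-DEMIRs (union over tissues): 40
  BWM   20 / 29 tested (69.0%)
  Coel  10 / 30 tested (33.3%)
  ...
shared Age-DEMIRs by >=k tissues: 40 18 9 2 0
recall of planted effects: 0.91 (20/22)
```

40 of 60 miRNAs change significantly with age in at least one tissue; the
number shared by k tissues decays with k (tissue-specific ageing); 20 of
the 22 planted 4-fold effects are recovered with the right direction.
`05_ev_sorting.R` prints:

```
detected miRNAs: EV 59 / worm 60
EV age-DE: 25 up / 17 down
secretion classes: promoted 19, suppressed 11, stable 27, undetermined 3
Spearman of D1 loading ratio vs planted sorting weight: 0.991 (n = 59)
```

so the recovered EV loading ratios rank-match the planted sorting weights
almost perfectly, and the promoted/suppressed classes land near the
planted 30%/30%. Stage outputs are tidy TSVs under `results/analysis/`.

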