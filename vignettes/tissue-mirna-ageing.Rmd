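---
title: "Methods: tissue-resolved miRNA ageing and inter-tissue trafficking"
author: "mirflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-resolved miRNA ageing and inter-tissue trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirflux)
```

# The analysis

mirflux implements a tissue-resolved analysis of miRNA ageing in
*C. elegans*. The organism is profiled at day 1 (D1, young adult) and day 8
(D8, aged, post-reproductive) in five somatic tissues — neurons (Neu),
intestine (Int), body wall muscle (BWM), hypodermis (Hyp) and coelomocytes
(Coel) — with three small-RNA replicates per tissue and age, plus whole-worm
and extracellular-vesicle (EV) UMI libraries. Five questions are asked of
these data, each a stage of the pipeline:

1. **Which miRNAs change with age in which tissue?** (Age-DEMIRs)
2. **Which miRNAs are present in tissues that do not transcribe them?**
   (PITT-miRs: potentially inter-tissue transported)
3. **What does the tissue-to-tissue trafficking network look like, and
   which flows are larger or smaller than chance?**
4. **Is secretion into EVs selective, and does ageing change it?**
5. **Which genes do these miRNAs regulate, and from inside or outside the
   tissue?**

# Normalization and detection

Mature miRNAs are short and essentially equal-length, so TPM reduces to a
per-million share of each library's miRNA-mapped reads: `compute_tpm()`
makes every column sum to 10^6. Cross-sample comparability is then enforced
by quantile normalization of log2(TPM + 1) (`log2_quantile_normalize()`).
The reference distribution is the mean of the column-sorted values; tied
values receive the mean of the reference quantiles they jointly occupy,
which makes the transform deterministic, order-independent and idempotent.
The pseudocount of 1 is a standard choice, recorded in the configuration.

A miRNA counts as *expressed* in a (tissue, age) group when its counts
exceed five reads — a strict inequality. Whether the rule is applied to the
replicate mean (default), to any replicate, or to all replicates is not
derivable from the detection rule alone, so `call_detection_reads()` takes
`group_rule = "mean" | "any" | "all"`; the mean rule feeds the group-level
T/E contrast while per-replicate calls (count > 5 in that sample) feed the
replicate-level flow table. UMI libraries use a different rule — a group is
detected when the UMI *sum* over its three replicates reaches 10, an
inclusive bound (`call_detection_umi()`).

QC ordination (`ordination_qc()`) runs PCA on centered features, computes
the sample–sample Pearson matrix and clusters samples by average linkage on
correlation distance (1 − r). The linkage is a fixed default; only the
correlation itself is prescribed by the procedure.

# Age differential expression

Counts at n = 3 per group are skewed and heteroscedastic, so each miRNA's
pooled D1 + D8 values (TPM + pseudocount) are first Box-Cox transformed,
with λ fitted by profile maximum likelihood on the pooled vector — a single
monotone transform keeps the two groups comparable; fitting per group would
not. The search interval is λ ∈ [−2, 2] (the conventional range; outside it
the profile likelihood of small samples often diverges towards degenerate
transforms), and a constant vector takes the tie-break λ = 1, i.e. the
shape-preserving shift x − 1. The transformed groups are compared by a
two-sided pooled-variance Student t-test.

Two significance criteria coexist in the source analyses: tissue-level
calls use p < 0.05 alone, while the worm/EV compartment calls additionally
require fold change > 1.5 or < 1/1.5. `call_age_demirs()` exposes this as
`mode = "tissue"` / `"compartment"`. Fold change is computed on the
untransformed group means (plus pseudocount), D8 over D1 — the transformed
scale would make folds non-comparable across miRNAs with different λ.
No multiple-testing adjustment is applied to the significance call (the
analysis is deliberately unadjusted); a BH FDR column is emitted for users.
The Age-DEMIR set of a tissue is the union of its up and down calls; the
global set is the union over tissues.

At n = 3 per group the Box-Cox/t procedure is mildly anti-conservative:
under a fully null generator its empirical type-I rate is ≈ 0.06 at a
nominal 0.05 (the acceptance suite measures this over 100 datasets × 200
miRNAs). This is a property of the published procedure itself, not of this
implementation; the log transform would be closer to nominal but is not
what the procedure prescribes.

# The T/E contrast and PITT-miRs

Transcription (T) is a gene-level boolean from promoter-reporter
(`PmiR::GFP`-style) observations per tissue and age, lifted to mature arms
through the annotation: both arms of a gene inherit its T calls. Expression
(E) is the group-level detection call. A mature miRNA is **PITT** in
(tissue, age) when E ∧ ¬T — present without local transcription. MiRNAs
whose gene has no interpretable promoter record are excluded up front
(`te_profiles()` warns; the analysable set can also be passed explicitly),
mirroring the exclusion of ambiguous reporter genes in the source data.
Whether reporter calls may differ between D1 and D8 is left open by the
source material; the map supports age-specific calls and collapses
gracefully when both ages are equal.

# The trafficking network and its permutation test

For each miRNA at an age, sources are tissues with E ∧ T and receivers are
tissues with E ∧ ¬T. The miRNA joins **every** directed source × receiver
edge — no fractional weights — because the network quantifies "number of
miRNAs transported in this direction" per direction, and one tissue can
take the same miRNA in from several others. A miRNA with receivers but no
internal source is attributed to an external "Other" node that only ever
acts as a source.

Edge significance uses a degree-preserving permutation null
(`permutation_flow_test()`): in each of n_perm = 1000 rounds, every
miRNA's source and receiver sets are redrawn as uniform random disjoint
tissue subsets of their observed sizes; "Other"-sourced miRNAs keep their
external source and only redraw receivers, since their true source lies
outside the modeled node set. This null preserves each miRNA's trafficking
multiplicity and the total flow mass, which is exactly what
over/under-representation of a direction should be judged against. The
plain alternative (global edge shuffling) ignores the per-miRNA structure;
the chosen null is documented here and isolated in one function should a
user want to swap it.

Each edge's null weight sample is then Yeo-Johnson transformed — the
power-transform family defined on all reals, appropriate because null
weights can be zero — with λ fitted per edge by maximum likelihood; the
observed weight is transformed with the same λ, and
z = (w'~obs~ − mean(null'))/sd(null'). The two-sided p comes from the
standard normal distribution and survival functions; an empirical
permutation p (add-one corrected) is emitted alongside for comparison.
Degenerate nulls (zero spread) yield z = NA, p = 1, flagged. Z-scores are
per *directed* edge; the undirected alternative is not computed. Under a
null-drawn network, |z| > 1.96 occurs on ≈ 5% of edges (measured over 100
datasets at n_perm = 200 in the acceptance suite); at n_perm = 1000 the
z of an edge with weight ≥ 5 varies by < 0.1 sd across seeds.

# EV loading and selective secretion

Within each compartment-age (Worm/EV × D1/D8), the replicate-mean UMI of
each detected miRNA is divided by the sum over the detected set, giving
relative abundances that sum to one — shares of the detected miRNAome. The
**EV loading ratio** of a miRNA at an age is its EV share over its worm
share; the **age change** is the D8 ratio over the D1 ratio. Secretion is
*promoted* when the age change strictly exceeds 2, *suppressed* when
strictly below 1/2, *stable* in between (exactly 2-fold is stable by the
strict reading of "more than 2-fold"). MiRNAs detected in only one
compartment at an age get no ratio and the class *undetermined* — division
pathologies are refused rather than patched, matching an analysis of the
jointly detected set. Replicate means (not pooled UMIs) are the default
denominator basis; the two differ only through unequal library sizes.

# Target inference and autonomy

A miRNA-gene pair is a candidate when the gene's 3'UTR carries at least one
canonical seed site: the site core complements miRNA positions 2–7, and the
flanks decide the type (8mer > 7mer-m8 > 7mer-A1; each core occurrence is
reported once, as its strongest type). Context scoring, conserved-branch
scoring and 3'-supplementary pairing are deliberately out of scope — the
site table acts as a filter, and an externally computed TargetScan-style
table with the same columns can be substituted.

A candidate passes when the Pearson correlation between the miRNA's and the
gene's log2 condition means across the 10 tissue × age conditions is below
−0.2. Condition means (rather than the 30 replicate samples) are the
default axis: the question is whether the *age- and tissue-dependent
profiles* mirror each other, and replicate-level correlations would be
dominated by within-group noise. Pairs with a constant profile on either
side are excluded with a reason code rather than given r = NA downstream.

A passing pair is called per (tissue, age) where both members are expressed
there. The call is **non-autonomous** when the miRNA is PITT in that tissue
and age — regulation by an imported miRNA — and autonomous otherwise; the
two classes partition the calls exactly. Target genes are annotated against
an ageing-gene list (fraction reported) and tested for category
over-representation with one-sided Fisher exact tests per category at each
of the three annotation levels, against the background of genes expressed
in the corresponding tissue-ages (a whole-annotation background is a
documented alternative); raw p-values at 0.05 decide significance, with a
BH FDR column emitted per level.

# The synthetic-data generator

`simulate_mirnaome()` generates the full data bundle with known truth. What
it emulates, and what it chooses where the study conditions leave freedom:

* **Design**: 5 tissues × 2 ages × 3 replicates; worm + EV UMI libraries
  with 3 replicates each; ~60 mature miRNAs from ~48 genes (some genes
  contribute both arms), 300 genes with UTRs.
* **Counts**: negative-binomial reads (dispersion 0.1, typical of
  over-dispersed small-RNA counts) around per-(miRNA, tissue, age) expected
  levels; UMI counts are multinomial draws from expected shares (UMI
  sampling is closer to without-replacement molecule counting than to NB).
  Expected levels are log-normal (median ≈ 300) with a floor of 50
  wherever a miRNA is expressed, so that detection failures reflect the
  rules, not baseline draws.
* **Transcription**: each gene is transcribed in 1–3 tissues; 15% of genes
  gain or lose one tissue at D8 (age-dependent promoter activity).
* **Age effects**: 30% of miRNAs change 4-fold (up or down) at D8 in their
  transcribed tissues.
* **Transport**: half of the miRNAs are transported; receivers are drawn
  disjoint from sources and carry 20% of the mean source level —
  transported miRNAs sit well below their source tissue, as observed for
  muscle-derived miR-1 in other tissues.
* **EV sorting**: log-normal sorting weights (sd 1 on the log scale),
  normalized so the worm-share-weighted mean weight is 1 per age — the
  loading ratio then recovers the planted weight directly. 30% of miRNAs
  get a 3× D8 boost and 30% a 3× reduction, mirroring roughly balanced
  secretion classes. Because EV composition is a share vector, boosting
  many miRNAs at once raises the normalizing denominator and compresses
  every realized ratio change; the truth table therefore records both the
  nominal mechanism (`shift_class`) and the realized class implied by the
  normalized weights (`secretion_class`), and recovery is judged against
  the latter.
* **Targets**: 100 planted pairs; a target gene's expected expression is
  depressed by 1.5 log2 units per standard deviation of its miRNA's
  standardized cross-condition profile, which yields strongly negative
  correlations without driving the gene below detection. UTRs are uniform
  random with sites planted at interior positions; accidental cores of
  *any* panel miRNA are removed by iterative point mutation outside
  planted ranges, and panel seeds are pairwise-distinct hexamers — so the
  planted truth is exact and false discoveries can be measured cleanly.

What the generator does **not** emulate: real worm sequence composition
(UTRs are uniform random, so background site frequencies are lower than in
genomic 3'UTRs), mapping and quantification noise upstream of the count
matrix, adapter/sequencing artifacts, isoform structure, batch effects, and
any tissue-specific EV uptake preference. Passing the recovery tests
therefore shows the pipeline's statistics behave as designed under the
modeled noise, not that real-data performance will match these numbers.

# Problem sizes and numerical choices

The test and acceptance workloads use 60 miRNAs / 300 genes per dataset
(the default fixture builds in about two seconds), 100 datasets of 200
miRNAs for the type-I calibration, 100 null networks at n_perm = 200 for
the z calibration, 20 seeded datasets for parameter recovery, and the full
4^10 decamer space for the seed-matcher equivalence check — sizes chosen so
the whole battery completes in a few minutes while keeping Monte-Carlo
error well inside the asserted bands. All randomness flows from explicit
seeds; deterministic stages are byte-identical across reruns, stochastic
stages for a fixed seed.

Numerical conventions collected in one place: pseudocount 1 before logs and
fold changes; strict `>` for read detection and secretion folds, inclusive
`>=` for the UMI sum; power-transform λ searched in [−2, 2] with λ = 1 for
constant input; zero pooled variance in the t-test gives p = 1 (equal
means) or p = 0 flagged degenerate; quantile-normalization ties take the
mean of their reference quantiles; doubles are serialized with 17
significant digits so written fixtures reload bit-identically.

# Limitations

* The T/E contrast inherits the sensitivity mismatch between promoter
  reporters and sequencing; the PITT definition cannot distinguish
  transport from a reporter that under-reports transcription.
* The trafficking network is a presence/absence construction; edge weights
  count miRNA species, not molecules, and the permutation null fixes each
  miRNA's multiplicities by design.
* The EV analysis cannot attribute vesicles to a source tissue.
* The compartment DE default (Box-Cox t-test on per-million shares) is a
  deliberate consistency choice keeping tissue and compartment calls on
  one footing; `umi_proportion_test()` offers a count-based pooled
  two-proportion z alternative, but the exact internals of count-ratio DE
  tools sometimes used on UMI libraries are out of scope.
* Seed matching is canonical-site only; non-canonical and 3'-supplementary
  sites are invisible to it.
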