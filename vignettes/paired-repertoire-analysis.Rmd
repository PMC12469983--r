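---
title: "Paired single-cell TCR repertoire analysis: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired single-cell TCR repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pairedTCR analyses single-cell alpha/beta T cell receptor (TCR) repertoires
in paired longitudinal designs: each patient contributes one sample per
condition (labelled `pre_GFD` / `post_GFD` after the dietary-intervention
setting the package was built around, but any two-condition contrast fits).
This vignette explains the models and conventions behind each stage, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## From contigs to paired cells

Input is one contig table per sample, in either the 10x Genomics
`filtered_contig_annotations.csv` dialect or an AIRR Rearrangement TSV.
Reading keeps only productive TRA/TRB contigs (and, for 10x, rows flagged
`is_cell` and `high_confidence`), strips allele suffixes from segment calls
because all downstream analysis is at gene resolution, and rejects rows
whose CDR3 amino-acid sequence leaves the 20-letter alphabet or whose V
call contradicts the locus. Rejections are counted, not silently dropped.

Chain filtering resolves each barcode to exactly one alpha/beta pair: per
locus the highest-UMI chain wins, UMI ties break on the lexicographically
smallest nucleotide CDR3 (so the result is a pure function of the record
*set*, not of file order), and barcodes missing either locus are removed.
One alpha/beta pair per cell is the unit every downstream statistic
assumes. The filter log records input barcodes, surviving cells, cells
lacking each locus, extra chains dropped, and cells without metadata —
making any discrepancy between upstream QC counts and analysed cells
auditable.

## Clonotype definitions

Four clone keys are supported; all combine both chains with the TRA
component first:

* `gene` — V/J/C segments of both chains;
* `nt` — both nucleotide CDR3s;
* `aa` — both amino-acid CDR3s;
* `strict` — genes plus nucleotide CDR3s (**default**).

The strict default is the most conservative reading of "unique combination
of chain sequences"; the gene-level key is exposed because repertoire
pipelines commonly report it. Every output records the mode used, and key
refinement can only split clonotypes (tested as an invariant).

Clone sizes are binned as Single [1], Small [2–5], Medium [6–20],
Large [21–100], Hyperexpanded (>100); only the >100 boundary is anchored in
the source setting (hyperexpanded clones absent), the inner edges follow
the conventional single/small/medium/large vocabulary and are configurable.
The unique-clone fraction defaults to singleton clonotypes over clonotypes;
the cells denominator is available because the quantity is reported both
ways in the literature.

## Diversity, bootstrap, and overlap

Six indices are computed by direct summation over clone proportions
$p_i = n_i/N$: Shannon entropy $H=-\sum p_i\ln p_i$ (nats), inverse Simpson
$1/\sum p_i^2$, Gini–Simpson $1-\sum p_i^2$, normalized entropy $H/\ln S$
(defined 0 when $S=1$), bias-corrected Chao1
$S + f_1(f_1-1)/(2(f_2+1))$, and ACE with the standard rare-abundance
cutoff of 10 (falling back to Chao1 when the rare-clone coverage is zero).
The bias-corrected Chao1 is the default because the classic
$S+f_1^2/2f_2$ form is undefined on the many repertoires with $f_2=0$.

Samples of unequal size are compared by bootstrap downsampling: `B`
replicates (default 100) of `depth` cells drawn with replacement from the
cell-level multiset, all indices recomputed per replicate, mean and sd
reported next to the point estimates. The default depth is the smallest
sample size in the comparison; both `B` and the depth policy are recorded
in the output because neither is canonical. Condition contrasts use the
classical paired t-test on per-patient values ($df=n-1$); zero-variance
differences are flagged as undefined rather than given a fabricated p.

Repertoire overlap uses the **Morisita–Horn** index on proportions,
$C = 2\sum x_iy_i / ((\sum x_i^2/X^2 + \sum y_i^2/Y^2)XY)$, because the
classic Morisita index on counts can exceed 1 and the intended scale is
[0, 1] (0 = disjoint, 1 = identical composition). Values are clamped
against floating-point rounding.

## CDR3 sequence features

Positional profiles left-align sequences and divide position $p$ by the
total weight of sequences of length $\ge p$, so each covered position is a
proper distribution over the 20 amino acids (the alternative — a global
denominator with NA padding — makes trailing positions sum below 1 and was
rejected). Positional entropy is normalized by $\ln 20$ to [0, 1].
Atchley-factor profiles are the per-position weighted means of the five
published factor scores (Atchley et al. 2005, PNAS 102:6395), shipped as
the exported `atchley_factors` matrix. Weights default to clone cell
counts (repertoire-level composition); weight 1 per unique sequence gives
the clonotype-level reading. K-mer spectra slide a width-`k` window
(default 3, both nucleotide and amino-acid alphabets) with clone-size
weights and report within-sample percentages.

## Gene pairing enrichment

The analytical core is the contrast between *marginal* gene usage and
*joint* pairing. Usage tables are dense over the union of observed genes
plus configured pools, so per-condition vectors are conformable. Pairing
arrays count units (cells by default; clonotypes collapse each
within-sample clone to one unit) per gene pair and stratum.

Two stratified tests are provided:

* `cmh_2x2xk()` — the classical Cochran–Mantel–Haenszel statistic with
  optional continuity correction, for 2×2×K presence tables;
* `cmh_general()` — the generalized CMH test of general association for
  I×J×K arrays: per stratum the $(I-1)(J-1)$ vector of observed minus
  expected counts under independence given margins, with its
  multiple-hypergeometric covariance; the summed quadratic form is
  chi-square with $(I-1)(J-1)$ df. Singular covariances are handled by an
  eigendecomposition pseudo-inverse with df reduced to the rank, and the
  result notes the reduction.

Because the axis roles of "a three-dimensional contingency array" are
ambiguous, the pipeline runs the arrangement that directly answers "does
the pairing distribution differ between conditions" — pairing category ×
condition, stratified by patient — and also emits TRAV × TRBV stratified
by condition for comparison; each result is labelled with its arrangement.
The same default arrangement is applied to TRAV–TRAJ and TRBV–TRBJ
pairings.

Per-pair tests build a 2×2 presence table (pair / other × pre / post) per
gene pair. The two-sided p comes from full hypergeometric enumeration
(probabilities $\le$ the observed one, with a relative tolerance of 1e-7
on the comparison). The odds ratio is $ad/bc$ — pre odds over post odds,
so OR < 1 reads "enriched post" — with the Haldane–Anscombe 0.5 correction
when any cell is zero; a pair absent from both conditions is reported as
OR 1 / direction `none`, since the correction would otherwise manufacture
a direction from the stratum totals alone. The conditional-MLE odds ratio
was rejected as needlessly heavier for a screening statistic; the
difference is documented here. Benjamini–Hochberg is the default
multiplicity adjustment (Bonferroni available).

## CDR3 similarity clustering

Clonotypes are clustered per group (default: per patient, conditions
pooled) on the amino-acid CDR3 of one chain (TRA by default). Similarity
is $1 - d_{\mathrm{Lev}}/\max(|a|,|b|)$ — the max-length denominator
bounds it in [0, 1] — and edges form at similarity $\ge$ 0.85. Nodes are
deduplicated CDR3 sequences (multiplicity kept as node weight) so the
pre-only / post-only / shared status of a sequence is well-defined;
clusters are connected components. A length-difference prefilter skips
pairs whose length gap already exceeds the edit budget; it is exactly
equivalent to the unfiltered computation because the edit distance is
bounded below by the length difference (tested).

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the package targets: 5
patients × 2 conditions, per-sample cell counts on the 1500–3500 scale,
clonal contraction after intervention, and condition-specific pairing
shifts. Per patient, V/J usage vectors are drawn from a Dirichlet around
cohort-level means; joint TRAV×TRBV pair probabilities are
$p_{ij} \propto p_i q_j e^{\beta_{ij}}$ with $\beta$ applied only in the
affected condition, so marginal usage is left structurally unchanged while
the joint distribution tilts — the core mechanism the pairing stage must
detect. Pre-condition clone sizes mix a truncated-geometric body on 1–5
(singletons dominate) with a uniform expanded tail on [6, 100]; no
hyperexpanded clone is emitted by default. Every pre clone persists with
probability `persistence_prob` at size
$\max(1,\mathrm{round}(s \cdot \mathrm{contraction\_factor}))$, and the
post sample is filled to its exact target with novel singletons drawn from
the post-condition pair distribution. Applying persistence and contraction
to *all* clones (not only expanded ones) is what makes the null
configuration (contraction 1, persistence 1, no effects) reproduce the pre
clone-size multiset exactly — the generator's strongest self-check.
Defaults: contraction 0.3 and persistence 0.6, reflecting the strong
top-clone reduction and partial clone turnover the design emulates;
expanded fraction 0.02, putting roughly a third of pre-condition cells in
expanded clones, predominantly labelled CD8 (`expanded_cd8_prob` 0.8) as
expansions concentrate in the cytotoxic compartment.

CDR3s are anchored `C`…`F` with uniform interiors and triangular lengths
on [8, 20] (mode 14), so positional-entropy profiles show the low-entropy
termini the feature stage must detect; nucleotide junctions are uniform
codon back-translations (composition realism is irrelevant to the
statistics tested). All randomness flows from one seed through a fixed,
documented draw order; identical configurations are byte-identical.

What the generator does **not** emulate: germline-encoded CDR3 sequence
similarity (clones are unrelated strings, so clustering finds few
cross-clone edges), thymic selection and HLA restriction, realistic codon
usage, shared public clonotypes between patients (between-patient overlap
is essentially zero by construction), and transcriptome-derived subset
structure (labels are sampled, not inferred). Passing the simulation-based
tests therefore demonstrates that the estimators recover known effects
from data with the study's *statistical* structure, not that the
biological realism of any upstream step is validated.

## Validation design and problem sizes

The test suite validates every estimator against an independent route:
diversity indices against a naive loop oracle (and vegan where available),
the Fisher p against `fisher.test` and an exhaustive
binomial-coefficient enumeration over all 2×2 tables with $n \le 40$, the
CMH statistics against `mantelhaen.test` and the 2×2×K closed form, and
the edit distance against a memoized recursion, exhaustively for strings
of length $\le 4$ over a 3-letter alphabet.

Recovery properties run at the emulated study scale: 100 seeds of the
default 5-patient cohort for the within- versus between-patient overlap
separation, and 50 seeds for the contraction contrast (unique-clone
fraction up in all patients; paired t-test rejecting at $\alpha = 0.05$).

The pairing-shift recovery check uses a dedicated *pairing-isolation*
cohort: one patient, 2000 cells per condition, a 10×10 gene panel with
near-uniform usage, no clonal expansion and full clone turnover, and two
injected effects of $|\log \mathrm{OR}| = \ln 8$ (one per direction). The
reduced panel is a power consideration, decided from the design rather
than from data: ranking pairs by $|\log \mathrm{OR}|$ is only a meaningful
recovery criterion when expected per-pair counts (~20 here) keep
zero-count cells rare, because the Haldane correction assigns a zero-count
pair $|\log \mathrm{OR}| \approx \log(2c+1)$, which exceeds $\ln 8$
whenever the opposite condition holds 4 or more cells. With 20-gene
panels (expected count ~5) the ranking measures that correction artifact,
not recovery. The type-I companion check runs the same cohort without
effects and requires the mean Benjamini–Hochberg-significant fraction to
stay at or below 0.05 over 100 seeds.

## Known limitations

* Cell-level pairing tests treat cells as independent units; clonal
  expansion makes counts over-dispersed, so p-values on the cells unit are
  anti-conservative for expanded repertoires. The clonotypes unit is the
  conservative alternative and both are recorded in outputs.
* The Haldane-corrected odds ratio is biased toward the null for large
  true effects and its magnitude depends on stratum totals when a cell is
  zero; directions are robust, magnitudes near zero counts are not.
* Bootstrap downsampling biases richness-sensitive indices (Chao1, ACE,
  $S$) downward by construction; the bootstrap means are comparable across
  samples at equal depth but are not unbiased estimates of the full-sample
  quantities.
* `cmh_general` on the pairing × condition arrangement can involve
  hundreds of degrees of freedom; with few patients its asymptotics are
  approximate, which is why the per-pair exact tests accompany it.
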