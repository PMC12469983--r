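# pairedTCR

Paired-chain single-cell T cell receptor (TCR) repertoire analysis for
longitudinal cohort designs — each patient sampled under two conditions
(e.g. before and after a dietary or therapeutic intervention).

The package is aimed at immunogenomics analysts working with 10x Genomics
V(D)J contig annotations or AIRR Rearrangement tables who want, in one
tested toolchain:

* **chain filtering** to exactly one α/β pair per cell (max-UMI rule,
  deterministic tie-breaks, auditable filter log);
* **clonotype calling** under gene / nucleotide / amino-acid / strict key
  definitions, with size bins, unique-clone fractions, CDR3 length
  spectra, top-clone flows and pre/post scatter tables;
* **diversity and evenness**: Shannon entropy *H* = −Σ *p*ᵢ ln *p*ᵢ,
  inverse Simpson 1/Σ *p*ᵢ², Gini–Simpson 1 − Σ *p*ᵢ², normalized entropy
  *H*/ln *S*, bias-corrected Chao1 *S* + *f*₁(*f*₁−1)/(2(*f*₂+1)), and ACE
  (rare cutoff 10), with bootstrap downsampling to a common depth and
  paired t-tests across patients;
* **repertoire overlap** via the Morisita–Horn index
  *C* = 2Σ*x*ᵢ*y*ᵢ / ((Σ*x*ᵢ²/*X*² + Σ*y*ᵢ²/*Y*²)·*X·Y*) ∈ [0, 1];
* **CDR3 sequence features**: positional amino-acid composition, entropy
  normalized by ln 20, Atchley-factor profiles, weighted k-mer spectra;
* **gene-pairing enrichment** — the headline analysis: dense TRAV×TRBV
  (and TRAV–TRAJ, TRBV–TRBJ) contingency arrays, the generalized
  Cochran–Mantel–Haenszel test of general association (with 2×2×K closed
  form), per-pair Fisher exact tests with Haldane–Anscombe odds ratios and
  Benjamini–Hochberg adjustment — built to detect pairing shifts even when
  marginal gene usage stays stable;
* **clonal clustering** of CDR3 amino-acid sequences at normalized
  Levenshtein similarity ≥ 0.85, with per-condition cluster composition;
* a **seeded synthetic paired-cohort generator** with exported ground
  truth (clone fates, true pairing log-odds), so the whole stack is
  testable without any protected patient data;
* `run_pipeline()`, orchestrating all stages into plain-text tables plus
  a manifest whose hash certifies end-to-end determinism.

## Worked example

```r
library(pairedTCR)

cfg <- sim_config(n_patients = 2, cells_per_sample = 1000, seed = 1)
coh <- simulate_cohort(cfg)
coh
#> Synthetic paired TCR cohort
#>   2 patients, 4 samples, 4000 cells (seed 1)
#>   pairing effects: 6; contraction 0.30, persistence 0.60

cells <- cohort_cells(coh)            # standardize + filter + metadata
tabs  <- call_clonotypes(cells)       # strict clone key, per sample

round(diversity_profile(tabs[["PT01|pre_GFD"]])[
  , c("S_obs", "H", "inv_simpson", "gini_simpson", "norm_entropy")], 3)
#>   S_obs     H inv_simpson gini_simpson norm_entropy
#> 1   363 4.712      28.226        0.965        0.799
round(diversity_profile(tabs[["PT01|post_GFD"]])[
  , c("S_obs", "H", "inv_simpson", "gini_simpson", "norm_entropy")], 3)
#>   S_obs     H inv_simpson gini_simpson norm_entropy
#> 1   903 6.606      321.75        0.997        0.971
```

After the simulated intervention the same patient's repertoire is richer
(363 → 903 clonotypes at equal depth) and far more even (normalized
entropy 0.80 → 0.97): the expanded clones contracted and novel singletons
took their place. The unique-clone fraction moves accordingly
(0.606 → 0.987), while overlap separates paired from unrelated samples:

```r
morisita_overlap(tabs[["PT01|pre_GFD"]], tabs[["PT01|post_GFD"]])  # 0.399
morisita_overlap(tabs[["PT01|pre_GFD"]], tabs[["PT02|pre_GFD"]])   # 0
```

The pairing stage recovers the injected condition-specific TRAV–TRBV
shifts (odds ratios are pre-over-post, so `enriched_post` means OR < 1):

```r
pt <- per_pair_fisher(pairing_array(cells))
head(pt[, c("gene_a", "gene_b", "a", "c", "odds_ratio", "p_adj", "direction")], 5)
#>       gene_a  gene_b   a  c odds_ratio    p_adj     direction
#> 219 TRAV26-1  TRBV28 106 12      9.272 7.10e-18 depleted_post
#> 334 TRAV26-2 TRBV7-2  77  9      8.858 1.42e-12 depleted_post
#> 294   TRAV21 TRBV6-1 107 45      2.456 4.06e-05 depleted_post
#> 239 TRAV26-2  TRBV30 122 58      2.175 1.16e-04 depleted_post
#> 211   TRAV10  TRBV28   6 36      0.164 1.92e-04 enriched_post
```

The full pipeline writes every stage table plus a deterministic manifest:

```r
res <- run_pipeline(run_config(simulate = list(seed = 7), seed = 7), "out/")
res$manifest$manifest_hash   # identical across reruns of the same config
```

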