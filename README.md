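# tbpsnp

Predicting the expression consequences of core-promoter variants from
TATA-binding-protein (TBP) affinity, and testing what evolution has done
with such variants.

## What it does, and for whom

Most well-characterized regulatory SNPs sit within ~70 bp upstream of a
transcription start site (TSS) and act through the binding affinity of
TBP for its promoter site: tighter binding, higher expression. `tbpsnp`
is for computational geneticists who want to

- score a 70-bp promoter allele for TBP affinity with a sliding-window
  model (position-weight matrix plus dinucleotide context: TA-richness,
  minor-groove width, melting propensity), reported as
  `-ln(K_D) ± δ` with the best site's location;
- compare a SNP's ancestral and minor promoter alleles and decide
  **deficiency** (predicted underexpression), **excess**, or
  **insignificant**, via the Fisher Z-score
  `Z = |v_wt − v_min| / √(δ_wt² + δ_min²)` and its two-sided normal
  p-value;
- map decisions to disease-direction markers (aggravate ↑ / relieve ↓)
  through a curated per-gene catalog, and tally markers per gene
  category (N_G, N_S, N_R, N_>, N_<, N_↑, N_↓);
- test tallies against the **neutral-drift criterion** (damaging variants
  should outnumber improving ones; exact one-sided binomial) and for
  **↑↓-equivalence** (exact two-sided binomial);
- cross-validate marker directions against domestic-vs-wild
  differential-expression tables: divergence from the nearest common
  ancestor → 2×2 lineage-by-effect table → Pearson χ², Fisher exact, and
  per-row exact binomials.

Seeded synthetic-data generators (promoters with planted TATA boxes,
SNP classes with ground truth, DEG tables with tunable associations)
make the whole chain testable offline, and packaged fixtures transcribe
the published 11-ortholog comparison and dataset sizes.

## Worked example

```r
library(tbpsnp)
model <- tbp_model()          # packaged PWM, scales, calibrated weights
model
#> TBP-promoter affinity model
#>   footprint L = 15 | strands: both
#>   consensus: TATAAAAAGGGGGGG
#>   weights:  w0=23, w_pwm=0.4, w_ta=0.35, w_mg=0.15, w_melt=0.25

# a synthetic 70-bp promoter with a TATA box planted at offset -30
spec <- synthetic_spec(seed = 42, n_promoters = 1)
promoter <- gen_promoters(spec)[[1]]
estimate_affinity(promoter, model)
#> -ln(KD) = 18.888 +/- 0.317 (best site at -30, strand +)
```

The estimate is the best window's score on the `-ln(K_D)` scale (larger =
tighter TBP binding), `± δ` the standard error of the top-20 window
scores; the scanner found the planted box at −30. Damaging the box's
first consensus base:

```r
compare_alleles(promoter, snp_spec("rsDEMO", offset = -30, "T", "C"), model)
#> rsDEMO (SYN0001)
#>   wt : -ln(KD) = 18.888 +/- 0.317
#>   min: -ln(KD) = 17.191 +/- 0.253
#>   Z = 4.186, p = 2.84e-05 -> deficiency (site damaged)
```

The minor allele significantly lowers predicted affinity: the SNP is
called a deficiency (underexpression) marker. Cross-validating the
packaged 11-ortholog fixture against its human disease annotations:

```r
fx <- fixture_table3()
crossval_report(fx$degs, fx$catalog)
#> Lineage x disease-effect cross-validation (11 ortholog pairs)
#>          aggravate relieve
#> domestic        10       1
#> wild             3       8
#>   Pearson chi2 = 9.214 (p = 0.0024); Yates chi2 = 6.769
#>   Fisher exact (two-sided) p = 0.00752
#>   row binomials: domestic p = 0.00586, wild p = 0.113
```

Expression shifts in the domestic lineages are strongly biased toward the
disease-aggravating direction (10 of 11; one-sided binomial p = 0.0059),
while the wild lineages show no such bias (p = 0.113). And a
selection-mode test on a marker tally — 46 site-improving vs 23
site-damaging markers:

```r
neutral_drift_test(46, 23)
#> exact binomial: k = 46 of n = 69 (p = 1/2)
#>   one-sided P(X >= k) = 0.00381; two-sided = 0.007621
#>   verdict: drift rejected (selection) at alpha = 0.05
```

Improving variants outnumber damaging ones far beyond what neutral drift
allows: selection against underexpression of these genes.

The end-to-end driver `run_pipeline(config)` chains all stages from
FASTA/TSV inputs and writes TSV/JSON reports plus a run log; see
`?run_pipeline` and the vignette in `vignettes/` for the model's
assumptions, parameter rationale, and calibration.

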