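# pulseDHS

Growth hormone (GH) reaches the male rodent liver in discrete plasma
pulses, transiently activating STAT5 every few hours; female plasma GH is
near-continuous. A subset of liver DNase-I hypersensitive sites (DHS)
opens and closes in phase with these pulses — **dynamic** DHS — while
other sex-biased sites stay constitutively open in one sex — **static**
DHS. `pulseDHS` is an R toolkit for discovering and characterizing these
two chromatin classes from DNase-seq cut-site data, for analysts working
on sex-biased or hormone-pulse-driven gene regulation:

* windowed differential accessibility testing between STAT5-high and
  STAT5-low livers (pooled G-test, |FC| > 2, FDR < 0.05, peak-union
  overlap), with PCA-based outlier rejection and a two-pass re-test;
* classification of a reference DHS catalog into dynamic/static x
  male/female/independent classes, plus hypophysectomy / GH-replacement
  response labels;
* normalized DNase-I cut-site aggregate profiles over 2-kb
  midpoint-centered windows (per-million reference-catalog reads, per
  region, LOWESS-smoothed, baseline-subtracted) and RiPPM scaling;
* annotation: TAD-constrained nearest-TSS target genes, chromatin-state
  assignment with a max-overlap/smaller-coordinate tie rule, STAT5
  binding labels, and exact-threshold PWM motif scanning;
* sex-biased gene calling and hypophysectomy response classes I/II;
* the ratio-of-ratios **enrichment score** with a two-sided Fisher exact
  test and Benjamini–Hochberg adjustment,

  ES = (a_in / a_out) / (b_in / b_out)

  (odds variant; a percentage variant is available for feature-overlap
  batches), scored against a static sex-independent background;
* a synthetic-data module that generates cut-site cohorts with the
  pulsatile/static structure the analysis assumes — including
  ground-truth labels — so every stage is testable without sequencing
  data.

## Worked example

Score a 2x2 enrichment table — dynamic male-biased DHS in the
enhancer-like chromatin state E6 versus a static sex-independent
background:

```r
library(pulseDHS)
tab <- contingency_table(604, 230, 24082, 40502)
round(enrichment_score(tab), 1)   # (604/230) / (24082/40502)
#> 4.4
signif(fisher_two_sided(tab), 3)
#> 6.36e-93
```

Run the simulated pipeline end-to-end on a small cohort (4 STAT5-high,
5 STAT5-low, 3 female samples; 860 DHS on a 4-Mb chromosome):

```r
cfg <- pipeline_config(seed = 1, sim = sim_config(
  seed = 1, genome = c(chrS = 4e6),
  n_dhs = c(dynamic_male = 80, static_male = 120, static_female = 60,
            dynamic_indep = 0, background = 600),
  n_high = 4, n_low = 5, n_female = 3, depth = 8e4, n_tads = 20))
res <- run_pipeline(cfg, outdir = tempfile())
#> simulate: 860 DHS, 12 samples
#> diff: 0 outlier sample(s) flagged
#> diff: 81 opening and 38 closing regions
#> classify: dynamic_male=79, static_male=121, dynamic_female=1,
#>   static_female=59, dynamic_indep=1, static_indep=599
#> profile: dynamic male-biased peak ratio high/low = 3.21
#> annotate: 247 DHS STAT5-bound
#> geneclass: 8 male-biased, 8 female-biased genes
#> enrich: 4 of 9 tests significant
```

79 of the 80 truly pulse-responsive DHS are recovered as dynamic; the
aggregate-profile peak ratio (3.21) approaches the generating 3.8-fold
(the gap reflects reference-catalog normalization at this small catalog
size; see the methods vignette). The enrichment table shows the planted
structure — dynamic male-biased DHS are the class most enriched for
STAT5 binding, STAT5 motifs and the E6 enhancer state:

```r
res$state$enrichment[1:3, c("foreground", "feature", "es", "padj")]
#>     foreground       feature       es         padj
#> 1 dynamic_male   stat5_bound 4.003443 4.421096e-27
#> 2 dynamic_male   stat5_motif 2.814978 1.978658e-17
#> 3 dynamic_male state_e6_male 2.180744 1.489056e-13
```

All stage outputs (BED/TSV) and an MD5 manifest are written to `outdir`;
re-running with the same config reproduces identical hashes.

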