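# sigfuge

Unsupervised detection of **differential isoform usage** from per-base
RNA-seq coverage.

Most tools that look for splicing or isoform differences compare known
groups (tumour vs normal).  But isoform switches often separate *unknown*
subsets of a cohort — a fraction of tumours silencing one promoter, or
skipping a cassette exon — and a supervised contrast never sees them.
`sigfuge` screens each gene locus of an RNA-seq cohort for such hidden
structure: it clusters the samples by the *shape* of their per-base
expression curves and attaches a simulation-based p-value for whether the
clusters are real, so that thousands of loci can be ranked and FDR-screened.

## Method

For one locus with union gene model of exonic length *d* and *n* samples:

1. **Extract** the *n × d* coverage matrix **X** over the exonic positions
   (from indexed BAMs, or a TSV of precomputed counts).  Introns are
   excluded; a spliced read counts only at its aligned exonic bases.
2. **Filter** samples in which the locus is essentially unexpressed:
   exclude sample *i* if > 90 % of its positions have zero coverage, or if
   its median depth over covered positions is < 5 reads.  These form the
   "low expression" class (plotted red).  Loci with fewer than 10
   surviving samples are not tested.
3. **Normalize**: scale each remaining curve to a common total coverage
   *C* (the median row sum), then take log2(x + 1).  This removes
   whole-gene expression differences so that clustering responds to curve
   shape — isoform usage — not amplitude.
4. **Cluster** with 2-means (Euclidean, best of 10 seeded Lloyd restarts)
   and summarize tightness with the **2-means cluster index**

   CI = Σₖ Σ_{i∈Cₖ} ‖xᵢ − x̄ₖ‖² / Σᵢ ‖xᵢ − x̄‖²,

   the within-cluster sum of squares over the total sum of squares.
5. **Test**: simulate 100 datasets from a single mean-zero Gaussian whose
   covariance eigenvalues are estimated from **X** (sample eigenvalues via
   the Gram matrix, regularised by total-variance-preserving soft
   thresholding against a difference-based background-noise estimate),
   compute each null dataset's CI with the identical 2-means policy, fit a
   Gaussian to the 100 null CIs, and report the lower-tail probability of
   the observed CI — small p-values mean the two clusters are tighter than
   a single Gaussian population explains.
6. Across loci, control FDR with Benjamini–Hochberg.

The package also ships the exon-level (RPKM) variant of the analysis, a
negative-binomial coverage simulator for two-isoform gene models with
power-study drivers, publication-style expression-curve plots
(red/green/blue classes, bold cluster medians, alternating exon shading),
and a small command-line interface (`inst/exec/sigfuge`).

## Worked example

Simulate a 100-sample cohort at a three-exon cassette gene (1200 bp,
per-base depth 100, NB dispersion 0.179) in which one half of the samples
expresses the cassette-containing isoform at proportion 0.75 and the other
half at 0.25, then run the full pipeline:

```r
library(sigfuge)

cfg <- sim_config(n1 = 50, n2 = 50, d = 1200, mu = 100, phi = 0.179,
                  template = "cassette3",
                  p1 = c(0.25, 0.75), p2 = c(0.75, 0.25))
m   <- simulate_dataset(cfg, seed = 1)
res <- sigfuge_gene(m, sp = sigclust_params(rng_seed = 1))
glance(res)
#> # A tibble: 1 × 10
#>   gene_id       n_total n_low  n_c1  n_c2    ci null_mean null_sd   pvalue flag
#>   <chr>           <int> <int> <int> <int> <dbl>     <dbl>   <dbl>    <dbl> <chr>
#> 1 sim_cassette3     100     0    66    34 0.321     0.430  0.0339 0.000681 ok
```

No sample is lowly expressed (`n_low = 0`); the curves split 66/34 (the
overdispersed isoform depths blur a handful of samples across the true
50/50 boundary), and the observed cluster index 0.321 sits about three
null standard deviations below the fitted null mean 0.430, giving
p ≈ 7 × 10⁻⁴: clear evidence for two isoform-usage groups at this locus.
Per-sample labels come from `tidy(res)`, and

```r
autoplot(res, m)
```

draws the overlaid expression curves with the two clusters in green/blue
and bold median curves.  Across many loci, `bh_adjust(pvalues, q = 0.05)`
computes q-values and rejections.

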