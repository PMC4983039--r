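# tipscore

Identify transcription-factor (TF) target genes from ChIP-seq or ChIP-chip
signal tracks — without depending on a peak caller.

## The problem and the method

Most target-gene callers start from a list of called binding peaks, which
makes the resulting target sets highly sensitive to the peak-calling method
and its parameters. `tipscore` instead implements the TIP approach (Target
Identification from Profiles): it uses the *entire* signal track, weighting
each gene's promoter signal by the TF's own genome-wide binding profile.

For each of *N* transcripts, let *f_g(x)* be the signal at offset
*x ∈ \[−L, L\]* from the transcription start site (TSS), read 5′→3′ in gene
orientation (default *L* = 10 kb). The method computes:

1. **Characteristic binding profile** — the aggregation plot
   *h(x) = (1/N) Σ_g f_g(x)*, normalized into a weight vector
   *w(x) = h(x) / Σ_x h(x)*.
2. **Regulatory score** — *s_g = Σ_x w(x) f_g(x)*, a continuous measure of
   how strongly the TF binds gene *g*'s promoter where this TF typically
   binds; scores are standardized to z-scores.
3. **Significance, two ways.** The classical route refers each z-score to
   a standard normal — simple, but conservative, because real score
   distributions are right-skewed or bimodal (background genes plus genuine
   targets). The refined route fits a two-component Gaussian mixture

   *ℓ(Θ | y) = Σ_i log( Σ_k w_k N(y_i | μ_k, σ_k) )*,  *k* = 1, 2

   by expectation–maximization and takes p-values from the upper tail of
   the **background** component (the one with the smaller mean). Both
   p-value sets are Benjamini–Hochberg adjusted and reported side by side;
   the mixture route is markedly more sensitive at the same FDR.
4. **Optional annotation** — binding-peak summit positions relative to the
   TSS of each called target (from a BED/narrowPeak file, or inferred from
   the track), and GO enrichment of the target set by the one-sided
   hypergeometric test, restricted to terms with fewer than 1000 genes.

Supported inputs: BedGraph, Wiggle (fixedStep/variableStep) and bigWig
tracks (gzip transparently handled), UCSC refGene-style or BED6 gene
annotation, BED3+/narrowPeak peaks, GMT gene sets.

## Worked example

Everything below runs on a synthetic genome with known ground truth — no
downloads needed. 200 genes on 2 chromosomes; 10% of genes get a Gaussian
binding bump (amplitude 10, sd 200 bp) at their TSS on top of exponential
background noise (mean 1):

```r
library(tipscore)

genes <- simulate_genome(n_genes = 200, seed = 42)
sim   <- simulate_track(genes, seed = 42)

res <- tip_run(sim$track, genes, out_dir = "demo_run",
               peaks = simulate_peaks(sim, genes),
               gmt   = simulate_gmt(genes, sim, seed = 42),
               seed = 42, organism = "toy")
res
#> TIP target-identification run
#>   transcripts scored: 200
#>   targets (mixture, FDR < 0.05): 21
#>   enriched GO terms (p < 0.05): 1
#>   panel files:
#>     demo_run/run_summary.tsv
#>     demo_run/binding_profile.tsv
#>     demo_run/zscore_density.tsv
#>     demo_run/target_genes.tsv
#>     demo_run/go_enrichment.tsv
```

The mixture fit separates background from targets cleanly:

```r
tidy(res$fit)
#> # A tibble: 2 × 4
#>   component  weight   mean    sd
#> 1 background    0.9 -0.327 0.184
#> 2 target        0.1  2.94  0.213
```

20 of the 21 called targets are the implanted ones (the generator implanted
20); the single-normal route calls 19 at the same threshold on this easy
fixture, and far fewer when the background is tight (see the vignette). The
GO panel ranks the deliberately target-enriched synthetic term first
(15/20 of its genes are targets, p ≈ 5e−14). Diagnostic plots:

```r
library(ggplot2)
autoplot(res$profile)   # aggregation plot: mean signal vs distance from TSS
autoplot(res$fit)       # z-score histogram + fitted mixture components
```

Thresholds can be changed without recomputing scores or refitting:

```r
res_loose <- tip_rethreshold("demo_run", fdr_threshold = 0.1)
```

A thin CLI over the same functions ships in `inst/cli/tipscore-cli.R`
(`run`, `rethreshold`, `simulate` subcommands).

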