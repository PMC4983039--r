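---
title: "Methods: profile-weighted TF target calling with a Gaussian-mixture background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-weighted TF target calling with a Gaussian-mixture background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipscore)
```

## The model

`tipscore` calls transcription-factor (TF) target genes from a genome-wide
binding-signal track rather than from pre-called peaks. The premise is that
a TF has a characteristic spatial binding preference around transcription
start sites (TSS), and that signal located where the TF typically binds is
better evidence of regulation than signal elsewhere.

For transcript $g$, let $f_g(x)$ be the per-base signal at offset
$x \in [-L, L]$ from the TSS, read 5′→3′ in gene orientation (minus-strand
windows are reversed). Three quantities follow:

* the characteristic profile $h(x) = \frac{1}{N}\sum_g f_g(x)$ — the
  aggregation plot over all $N$ transcripts;
* weights $w(x) = h(x) / \sum_x h(x)$, a probability-like vector;
* regulatory scores $s_g = \sum_x w(x)\, f_g(x)$, standardized to z-scores
  $z_g = (s_g - \bar{s})/\mathrm{sd}(s)$ (sample sd).

Because the weights sum to one, a gene with flat signal $c$ scores exactly
$c$; scores are linear in the track, so z-scores are invariant to
rescaling the signal (raw coverage vs normalized coverage).

### Significance: single normal vs two-component mixture

The classical route refers $z_g$ to the standard normal upper tail. That
is conservative whenever the score distribution is right-skewed or bimodal
— which it typically is, because the scores mix two populations:
background genes and genuine targets. The refined route models the
z-scores as a two-component Gaussian mixture with log-likelihood
$$\ell(\Theta \mid y) = \sum_{i=1}^n \log\Big(\sum_{k=1}^2
  w_k\, N(y_i \mid \mu_k, \sigma_k)\Big),$$
fitted by EM: the E-step computes posterior responsibilities
$\hat z_{ik} \propto \hat w_k N(y_i \mid \hat\mu_k, \hat\sigma_k)$
(normalized per observation) and the M-step updates
$\hat w_k = \sum_i \hat z_{ik}/n$,
$\hat\mu_k = \sum_i \hat z_{ik} y_i / \sum_i \hat z_{ik}$,
$\hat\sigma_k^2 = \sum_i \hat z_{ik}(y_i - \hat\mu_k)^2 / \sum_i \hat z_{ik}$.
After fitting, components are relabeled so component 1 has the smaller
mean; it is interpreted as the background (non-target) population, and
p-values are its upper tail: $p_g = 1 - \Phi\big((z_g - \mu_1)/\sigma_1\big)$.
When the background component is tighter than the pooled distribution
($\sigma_1 < 1$, $\mu_1 \le 0$ after standardization), these p-values are
uniformly smaller than the standard-normal ones for high z, which is
exactly where the sensitivity gain comes from. Both p-value sets are
always computed, Benjamini–Hochberg adjusted, and reported side by side;
the `method` switch only selects which one drives the target flag used by
peak annotation and GO enrichment.

### Peak annotation and GO enrichment

Given a BED/narrowPeak file, every peak overlapping a called target's
promoter window (any base of overlap; the file's own summit when provided)
is reported with its summit position relative to the TSS in gene
orientation and the track value at the summit. Targets without peaks are
reported by omission, deliberately: genes with appreciable but sub-peak
binding are a key class this method can call that peak-based methods miss.

GO enrichment uses the one-sided hypergeometric (Fisher exact) test of the
target set against the scored universe. Terms with 1000 or more annotated
genes (counted annotation-wide, before intersecting with the universe; the
bound is strictly `< 1000`) are excluded as uninformatively general. Raw
p-values drive the reporting threshold; BH-adjusted values are emitted as
an additional column for users who prefer them.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `half_width` (L) | 10000 | bp | a 20 kb TSS-centered window comfortably contains promoter-proximal binding while keeping profiles stable |
| `fdr_threshold` | 0.05 | — | conventional stringency; 0.1 is a common lenient alternative |
| `go_p_threshold` | 0.05 | raw p | GO terms are screened on raw p; BH column provided |
| `method` | mixture | — | the mixture route is the package's point; `single` retained for comparison |
| `max_term_size` | 1000 | genes | strict `<` cutoff excluding uninformative general terms |
| `tol`, `max_iter` | 1e-8, 500 | — | EM stopping rule on the change in log-likelihood |
| `restarts` | 5 | — | one deterministic quantile-split start plus 4 seeded random perturbations |

## Numerical choices

* **Coordinates.** Everything internal is 0-based half-open (UCSC table
  convention); Wiggle's 1-based starts are converted at parse time, and
  bigWig I/O converts at the rtracklayer boundary.
* **EM initialization.** The data are split at the 90th quantile: lower
  part seeds the background component, upper part the target component.
  This is deterministic and matches the expected shape (a dominant
  background plus a small high-score tail). Additional restarts perturb
  means, dispersions and weights at random under the user seed; the best
  final log-likelihood wins.
* **Variance floor.** $\sigma_k^2 \ge 10^{-4}$ guards the classic mixture
  likelihood singularity. A restart whose component weight or
  responsibility mass collapses is discarded; if every restart collapses,
  a single-Gaussian fallback is returned flagged `degenerate`, and mixture
  p-values fall back to the standard-normal route with a warning.
* **E-step in log space.** Posteriors and the likelihood use the
  log-sum-exp form, so extreme z-scores do not underflow.
* **Overlapping track intervals** are resolved last-writer-wins (file
  order) with a counted warning — deterministic, and tolerant of wiggle
  dialects that overlap at block seams. Negative values (log-ratio tracks)
  pass through with a summary warning; if the aggregate profile dips below
  zero, weights are computed on the profile floored at zero (warned), so
  they remain a probability-like vector.
* **fixedStep span.** When a `fixedStep` declaration omits `span`, the
  package assumes `span = step` (contiguous coverage), which is what files
  in the wild mean; `strict_span = TRUE` restores the formal UCSC default
  of 1.
* **Windows at chromosome edges** are retained; out-of-range bases
  contribute 0. Dropping such genes would make the scored universe depend
  on chromosome sizes, silently changing FDR denominators between runs.
* **Ties and ordering.** Targets are sorted by decreasing score with ties
  broken by transcript id; the summit of a flat (tied) peak region is the
  smallest in-window coordinate. Panel TSVs format doubles at 6
  significant digits so repeated runs are byte-identical; the cache keeps
  17 significant digits so re-thresholding reproduces the original tables
  exactly.
* **Summits outside the window.** A BED-supplied summit can fall outside
  the promoter window even though its peak overlaps it; in that case the
  summit is re-derived as the signal argmax within the peak–window
  intersection, keeping every reported summit inside both.

## Design decisions that were genuinely open

* **Per-transcript scoring.** Transcripts are scored individually and the
  gene symbol is carried for reporting; overlapping transcripts of one
  gene are *not* collapsed before profile building. Collapsing rules are
  annotation-dependent and would change the universe invisibly.
* **Profile from the scored universe.** The profile is built from the same
  genes that are scored (no held-out split), matching the single-pass
  behavior the method is known for. The circularity is mild — each gene
  contributes $1/N$ of the profile — and vanishes for large universes.
* **GO universe.** The universe is the set of scored gene symbols, not the
  whole annotation file: the test conditions on genes that could have been
  called.
* **No model selection.** The mixture is fixed at $K = 2$; users compare
  the single and mixture outputs directly rather than via BIC.
* **Signal semantics are not interpreted.** Coverage and fold-change
  tracks are both accepted; the value column is used as-is.
* **Re-thresholding scope.** `tip_rethreshold()` recomputes target flags,
  the target table, peak annotation for the new target set, and GO
  enrichment; scores, z-scores and the mixture fit are reloaded from the
  cache untouched.

## What the synthetic generator emulates — and what it does not

`simulate_genome()`/`simulate_track()` generate a toy genome (default 200
genes on 2 chromosomes, TSSs 25 kb apart) and a coverage-like track:
i.i.d. exponential noise on 10 bp tiles (nonnegative, right-skewed) plus a
Gaussian bump (default amplitude 10 over noise mean 1, sd 200 bp, centered
at the TSS) implanted at a random 10% of genes. Matching peak files carry
the exact implanted summits, and `simulate_gmt()` builds gene sets with a
deliberately target-enriched term and, on request, an oversized term
(padded with clearly labelled synthetic symbols) to exercise the size
filter. Everything is deterministic under `seed`.

The generator emulates the *statistical* structure the method relies on —
a two-population score distribution, strand-oriented promoter bumps,
skewed nonnegative background — but not read-level artifacts: no
mappability gaps, GC bias, fragment-length effects, overlapping genes, or
copy-number variation. Passing the end-to-end tests therefore demonstrates
correctness of the machinery and the claimed qualitative behaviors
(mixture ≥ single sensitivity, rank separation at high signal-to-noise),
not performance on any particular real dataset.

```{r example}
genes <- simulate_genome(n_genes = 100, spacing = 5000, half_width = 2000, seed = 1)
sim <- simulate_track(genes, seed = 1)
scores <- tip_score(sim$track, genes, half_width = 2000)
scored <- score_significance(scores, seed = 1)
glance(attr(scored, "fit"))
c(mixture = sum(scored$is_target_mixture), single = sum(scored$is_target_single))
```

## Problem sizes used by the test suite

The shipped tests validate: EM one-step agreement with a direct evaluation
of the update equations at $n \le 50$; likelihood monotonicity over 100
seeded fits at $n = 200$; parameter recovery of a
$0.9\,N(0,1) + 0.1\,N(4,1)$ mixture at $n = 10{,}000$ over 20 seeds
(median $|\hat w_1 - 0.9| < 0.02$, $|\hat\mu_2 - 4| < 0.3$); the
superset property of mixture over single-normal calls at fixed FDR over
50 seeded draws of 2000 standardized scores with a tight background;
end-to-end recovery at generator defaults over 10 seeds (mean sensitivity
≥ 0.9 at FDR < 0.05 with empirical FDR ≤ 0.1, plus complete rank
separation of implanted targets); exhaustive hypergeometric enumeration
for all configurations with universe ≤ 30; BH agreement with a reference
step-up on 1000 random p-vectors; byte-identical score tables across
BedGraph/Wiggle/bigWig encodings of the same coverage (values quantized to
1/64 so the bigWig float32 round trip is lossless); and score equality to
$10^{-9}$ under full genome mirroring. These sizes were chosen as the
smallest at which the properties are sharp, and `scripts/acceptance.R`
recomputes the same quantities from scratch.

## Known limitations

* The characteristic profile is TSS-centered: distal enhancer-driven
  regulation is invisible to the score.
* A TF whose aggregate profile is flat yields near-uniform weights and
  little resolving power; the aggregation plot is the diagnostic to check.
* With very few genes (tens) the mixture fit can be unstable; the
  degenerate fallback keeps the pipeline running but reverts to the
  conservative route.
* The `< 1000` GO size filter and raw-p thresholding follow the method's
  convention; users wanting FDR-controlled GO lists should use the
  provided `p_adjusted` column.
* `.rar` archives are not decompressed (no portable free implementation);
  gzip is handled transparently.
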