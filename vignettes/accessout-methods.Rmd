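---
title: "Chromatin accessibility outlier detection: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin accessibility outlier detection: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: the model and
its assumptions, every tunable parameter with its default and rationale, the
numerical safeguards, what the synthetic-data generator emulates, and the
known limitations. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The observation model

For sample $i$ and accessible region $j$, the read count $k_{ij}$ is modeled
as negative binomial,

$$k_{ij} \sim \mathrm{NB}\!\left(\mu = \hat k_{ij},\; r = r_j\right),
\qquad \operatorname{Var} = \mu + \mu^2/r_j ,$$

where $r_j$ is the per-region dispersion (large $r_j$ approaches Poisson)
and $\hat k_{ij}$ is the model expectation after confounder control. An
accessibility outlier is an entry whose observed count is incompatible with
this expectation.

**Normalization.** Sequencing-depth differences are absorbed by
median-of-ratios size factors: the reference level of region $j$ is its
geometric mean across samples (regions containing any zero are excluded so
the geometric means are positive), and $s_i$ is the median over reference
regions of $k_{ij}$ divided by that reference. This estimator is invariant
to a global rescaling of all samples and is the standard choice for count
data of this kind (DESeq2's estimator; the test suite checks our
implementation against DESeq2's when available). Counts then move to the
model scale

$$n_{ij} = \ln\!\frac{k_{ij}+1}{s_i}, \qquad
  x_{ij} = n_{ij} - \bar n_j ,$$

with $\bar n_j$ the per-region mean, so each region is centered at zero. The
inverse map, $\hat k_{ij} = e^{\hat x_{ij} + \bar n_j} s_i - 1$, floored at
$\varepsilon = 10^{-8}$, returns expectations to the count scale; the round
trip is exact (to floating tolerance) for positive counts.

**Latent confounders.** A linear autoencoder supplies $\hat x$: the encoder
is fixed to the top-$q$ principal axes of $x$ (it is never trained — PCA
*is* the encoder), its projection is concatenated with a known-confounder
design (one-hot categorical with first level dropped, z-scored numeric, and
a constant column), and a linear decoder maps the latent representation
back. The decoder is initialized by ordinary least squares and then refined
by a single bounded round of negative-binomial maximum likelihood per region
(Section 3). One alternating step — dispersion, decoder, dispersion — is
deliberate: a single round keeps the expectation surface close to the
least-squares solution, which is already near-optimal on the log scale, and
avoids the iterative schemes whose extra steps mostly chase their own
residuals.

**Test and calls.** The two-sided p-value doubles the smaller NB tail,

$$P_{ij} = 2\min\{\tfrac12,\, F(k_{ij}),\, 1 - F(k_{ij}-1)\},$$

capped at 1 (an undoubled variant, maximum $\tfrac12$, is available via
`double = FALSE` for comparison). The upper tail is evaluated in survival
form (`lower.tail = FALSE`); the textbook form $1 - F(k-1)$ cancels
catastrophically below $\sim 10^{-16}$ and would make all strong outliers
tie at zero. P-values are corrected per sample across regions with
Benjamini–Yekutieli (valid under arbitrary dependence; a matrix-wide scope
is available). An entry is called an outlier when `padj < 0.05`,
$|\log_2 \mathrm{FC}| > 0.5$, and the observed *or* expected count is at
least 50; the count rule suppresses calls in regions too shallow to be
interpretable.

## 2. Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_gap` | 200 | bp | peaks closer than this are merged so a read (shorter than the gap) can overlap at most one peak; gap exactly 200 is kept separate (strict inequality) |
| `min_mapq` | 10 | phred | alignment-quality filter at counting time |
| `high_count` | 100 | reads | a region must reach this in at least one sample |
| `min_reads`, `min_fraction` | 2, 0.5 | reads, fraction | replication filter: at least 2 reads in at least half the samples |
| `q` | 5 (or tuned) | dims | bottleneck size; `tune_bottleneck()` selects it by validation-mask auPRC |
| dispersion bounds | [0.01, 1000] | — | numerical stability and overfitting guard; equidispersed data clamps to 1000 |
| `alpha`, `min_l2fc`, `min_count` | 0.05, 0.5, 50 | — | outlier-calling thresholds (strict `<`, strict `>`, inclusive `>=`) |
| `p_inject` | 5e-4 | per direction | benchmark injection probability (0.1% of entries in total) |
| amplitude | $e^{N(3,1)}$ | region sd units | injected shift is $\sigma_j e^{N(3,1)} M_{ij}$ on the log scale |
| `winsor_c` | 3 | robust sd | pass-1 marginal winsorization of $x$ during fitting |
| `resid_c` | 5 | robust residual sd | pass-2 residual-based clipping and dispersion exclusion |
| `trust` | 1.5 | nat (log units) | saturation bound on the decoder likelihood update per sample |
| `mu_floor` | 0.5 | reads | minimum expectation inside the NB test |

## 3. Robustness machinery (and why it is necessary)

The injection benchmark is the stress test that shaped these choices. An
injected entry shifts one sample's log accessibility by
$\sigma_j e^{N(3,1)}$ — typically twenty region-standard-deviations, i.e.
observed counts that exceed expectations by many orders of magnitude.
Against such data three failure modes of the naive pipeline are provable and
were observed:

1. **Encoder hijack.** A single entry tens of sd away carries more variance
   than an entire region; the top principal axes align to the few largest
   aberrations instead of the genuine latent structure.
2. **Decoder chase.** The NB log-likelihood gain from moving $\hat k$
   toward an observed count $k$ grows like $k$ itself, so a converged
   per-region MLE will always sacrifice every other sample in the region to
   fit one absurd count — collapsing their expectations to the floor and
   producing astronomically significant false positives.
3. **Dispersion poisoning.** A single extreme count drags the region's
   dispersion MLE to the lower bound, after which genuine outliers in the
   same region (especially zero-count under-outliers) are shrugged off as
   heavy-tail noise.

The countermeasures, all inactive on clean data:

* **Two-pass fitting.** Pass 1 fits encoder and least-squares decoder on
  marginally winsorized data (per-region cap at `winsor_c = 3` robust sd,
  median ± c·1.4826·MAD). Pass 2 re-clips the *raw* data by pass-1
  residuals at `resid_c = 5` robust residual sd: genuine latent extremes
  are well predicted by pass 1 (small residual) and are restored unclipped,
  while aberrations (huge residual) stay capped near the model prediction.
  A marginal cap alone cannot make this distinction — it truncates real
  rank-$q$ structure and creates false positives of its own.
* **Residual-excluded dispersion.** Entries flagged in pass 2 are left out
  of the dispersion likelihood (a region keeps all entries if fewer than
  three would remain). This is the same logic as outlier exclusion before
  dispersion refitting in standard RNA-seq pipelines.
* **Bounded decoder update.** The likelihood refinement saturates each
  sample's log-prediction shift at `trust = 1.5` nat from the
  least-squares initialization. When shifts are moderate the clamp is
  inactive and the result is the exact (local) MLE — the unit suite
  verifies agreement with a dense 2-parameter grid search on clean data —
  but no single entry can move any sample's expectation more than
  ~4.5-fold in one round.
* **Prediction range clamp and test floor.** Model expectations never
  exceed the cleaned data's per-region range, and the NB test floors its
  mean at `mu_floor = 0.5` reads: an expectation that is numerically zero
  must not make a handful of observed reads look infinitely significant.

With these in place the detector is calibrated (null p-values uniform, KS
$< 0.05$ at $n = 10^5$) and recovers injected outliers at auPRC ~0.94 at
the benchmark scale, versus ~0.14 for the naive NB baseline.

## 4. The synthetic world

`simulate_counts()` draws from the same family the model fits: a rank-`q_true`
latent block $HW$ on the centered log scale (loadings $N(0, 0.5^2)$ per
factor, five factors by default — latent variation then dominates count
noise, emulating the strong cross-sample correlation structure of a
real cohort), per-region log-means log-uniform on [50, 500] reads (the
regime that survives the replication filter), dispersions log-uniform on
[2, 100], size factors log-uniform on [2/3, 1.5], optional batch effects,
and optional planted outliers using the same $\sigma_j e^{N(3,1)}$ scheme as
the injection benchmark. The truth bundle (mask, amplitudes, dispersions,
size factors, latent factors) makes parameter recovery assertable.

What the generator does *not* emulate: Tn5 insertion bias and fragment-size
structure, GC effects, sample-specific noise heterogeneity, copy-number
variation, and any mismatch between the NB family and real count noise. A
green test therefore establishes internal correctness — the estimator
recovers the parameters of its own generative family and the oracles agree
— not field performance on real chromatin data.

One consequence is worth stating explicitly because the benchmark test
computes it: in this exactly-NB low-rank world the PCA $|Z|$ baseline is
near-oracle, and the NB p-value ranking sits slightly below it (mean auPRC
~0.94 vs ~0.95 over ten masks) while both dwarf the naive NB test (~0.14).
The p-ranking is bounded for zero-count under-outliers — in a region with
dispersion $r$ and expectation $\mu$, observing zero reads can never be more
significant than $2(r/(r+\mu))^r$, which for $r \approx 2$ is only
$\sim 10^{-4}$ — whereas a Z-score rank has no such floor. On real data the
relationship reverses because unmodeled heteroskedastic residual structure
floods a Z-rank with false positives while the NB test absorbs it into
$r_j$; an exactly-NB simulation cannot show that effect, and we chose not to
engineer the generator to manufacture it.

## 5. Numerical and design decisions

* **NB parameterization**: size/overdispersion $r$ with variance
  $\mu + \mu^2/r$ — the convention whose bounds imply Poisson at the upper
  limit.
* **Eq. ambiguities resolved by inversion**: the log-normalization is read
  as $\ln((k+1)/s)$, the only parenthesization whose inverse matches the
  back-transform $e^{\hat x + \bar n} s - 1$; natural log on the model
  scale, $\log_2$ only for reported fold changes.
* **Size-factor reference**: per-*region* geometric mean across samples
  (a within-sample geometric mean would make the ratio depth-invariant and
  the estimator vacuous).
* **Ranking ties**: ascending p, then descending $|Z|$, then region index —
  stable and documented (`outlier_scores()`).
* **BY scope**: per sample across regions by default; matrix-wide optional.
* **Injection rounding**: injected counts are rounded to the nearest
  non-negative integer after back-transform (valid NB observations), and
  saturated at $2^{53}$ — the largest exactly representable integer —
  because amplitude draws far in the log-normal tail otherwise overflow the
  count scale.
* **auPRC**: interpolation-free step-wise average precision; ties share a
  threshold; verified against a brute-force enumeration of every cutoff.
* **Proximity pairs**: ordered pairs of distinct regions within a midpoint
  distance; the 2×2 Fisher table cross-tabulates the two statuses, and the
  sample odds ratio uses the Haldane–Anscombe 0.5 correction when a cell is
  empty (flagged).
* **Hi-C binning**: a region maps to the 5-kb bin of its midpoint; the
  contact score is the maximum over the 3×3 neighborhood of source and
  target bins, which also covers boundary-straddling regions.
* **ABC vicinity**: the candidate-target radius is not a settled constant
  in the field; the default is 1 Mb (the largest proximity window analyzed
  elsewhere in the workflow) and it is configurable.
* **Expression linkage**: features are per (gene, sample); genes with
  several promoters take the minimum p and the largest $|$fold change$|$;
  the distal feature is $\sum_{e \in g} |\mathrm{ABC}_{p \to e} \cdot
  \log_2 \mathrm{FC}_e|$ over the gene's distal enhancers. The downstream
  boosted classifier is deliberately out of scope: the package emits the
  exact feature table such a model consumes and evaluates any externally
  computed score column with the same precision-recall engine as the
  injection benchmark.

## 6. Known limitations

* The sorted-sweep counter assigns a read spanning two peaks (a violation
  of the merge-gap assumption) to the first peak and warns; it does not
  split or double-count.
* Counting treats each aligned record independently (mates of a pair count
  separately) and retains duplicates by default; both are flags, not fixed
  policy, because the right choice depends on upstream processing.
* The one-round bounded decoder update trades a small amount of likelihood
  on pathological regions for stability; `trust = Inf` restores the pure
  MLE if desired.
* Hi-C contact scores are taken as given (no ICE/KR normalization), and
  `.cool` containers are not read directly — contacts enter as a
  BEDPE-like pairs table.
* HDF5 containers are not written; all I/O is plain TSV.
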