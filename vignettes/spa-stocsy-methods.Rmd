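---
title: "Spatial clustering and STOCSY for untargeted NMR metabolite identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial clustering and STOCSY: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrspa)
```

# The problem

A one-dimensional ^1^H-NMR spectrum of a biological extract holds thousands
of datapoints along a chemical-shift (ppm) axis. Each metabolite contributes
one or more *structural units* — singlets, doublets, multiplets — at
characteristic positions, and the peaks of different metabolites overlap.
Untargeted identification asks: which metabolites are present, including
ones not annotated in any library? `nmrspa` answers this with a three-stage,
fully data-driven pipeline:

1. **Spatial clustering (SPA).** Contiguous datapoints arising from the same
   structural unit co-vary strongly across samples. A moving-window
   *correlation landscape* makes this visible, and thresholding it yields
   spatial clusters of datapoints.
2. **STOCSY grouping.** Statistical total correlation spectroscopy links
   clusters that co-vary across samples — the signature of resonances from
   the same molecule — by connected components of a thresholded
   cluster–cluster correlation matrix.
3. **Library matching.** Each group of clusters is matched against a
   resonance library; per metabolite, a *detection ratio* (matched library
   clusters / total library clusters in 0.5–4 ppm) above 0.55 calls the
   metabolite identified.

Because every tuning parameter is estimated from the input data (window
size from the PACF, clustering threshold from prediction strength, STOCSY
threshold from an internal-standard calibration), the pipeline runs without
operator intervention.

# The correlation landscape

For a samples × datapoints matrix $X$ and window size $k$, the landscape at
window start $j$ is the average of all $k(k-1)/2$ pairwise Pearson
correlations among columns $j,\dots,j+k-1$:

$$Q_j = \frac{2}{k(k-1)} \sum_{a<b} \rho\!\left(x_{\cdot j+a},\, x_{\cdot j+b}\right),
\qquad 0 \le a < b \le k-1 .$$

The value is assigned to the window's first variable; the last $k-1$
positions are undefined. Columns with zero variance (baseline-zeroed
regions) contribute 0 to every pair they enter: a zeroed baseline must read
as "no dependence", not as `NA`.

The landscape is stabilized by kernel smoothing with either the
Epanechnikov kernel $g(t)=\tfrac34(1-t^2)$ or the tricube kernel
$g(t)=(1-t^3)^3$, both supported on $|t|\le 1$ with
$t = \text{distance}/\text{bandwidth}$, weights renormalized over the
defined neighbours. Tricube is the default (it concentrates weight more
sharply at the centre, which resolves overlapped peaks better); the
bandwidth defaults to the window size $k$.

## Window size from the PACF

The window should span the lag range over which neighbouring datapoints are
genuinely dependent. `select_window_size()` computes the partial
autocorrelation function of the mean spectrum and returns the smallest lag
whose PACF lies inside the $\pm z_{0.975}/\sqrt{p}$ band, floored at 2 (a
window needs at least one pair). The per-sample PACF median is attached as
a consistency check, with a message when the two disagree materially. If
the PACF never enters the band by `max_lag` (default 50), `max_lag` is
returned with a warning. White-noise-like input therefore yields the floor
of 2, and strongly autoregressive input a small window, as the partial
autocorrelation of an AR(1) process cuts off after lag 1.

## Threshold selection by prediction strength

Raising the landscape threshold $\lambda$ splits and shrinks clusters;
lowering it merges them. The package chooses $\lambda$ by cluster
stability: the samples are split into two random halves, each half is
clustered independently, and each cluster of one half (with at least two
members) is scored by the fraction of its within-cluster variable pairs
that are also co-clustered in the other half. The per-direction statistic
is the *median* of those fractions over clusters; both directions are
averaged, and the split is repeated over `n_folds` folds (default 5, same
splits reused for every candidate $\lambda$). The chosen threshold is the
**lowest** grid value whose mean prediction strength is within one standard
error of the maximum. Singleton clusters are skipped in the median — their
pair set is empty and the normalizing factor $1/(m(m-1))$ is undefined at
$m=1$. A fold in which a half yields no clusters scores 0.

The one-SE rule deliberately prefers permissive thresholds, because an
over-split clustering is unstable under resampling while a merged one is
not. In practice the grid default is $\lambda \in \{0.30, 0.35, \dots,
0.95\}$.

## Cluster extraction

Clusters are maximal contiguous runs of smoothed landscape positions at or
above $\lambda$; runs shorter than `min_size` (default $k$, the natural
resolution floor — no narrower feature can be resolved by a $k$-window
statistic) are discarded.

# STOCSY on cluster representatives

Each cluster's representative intensity per sample is the mean of its
strict interior local maxima (plateau apexes at the plateau midpoint); a
cluster without an interior maximum — e.g. a truncated ramp — falls back to
its maximum intensity. Groups are connected components of the graph with an
edge wherever the Pearson correlation of representatives is at or above the
grouping threshold. The signed correlation is used, not $|r|$:
under a concentration-driven model, resonances of one molecule co-vary
positively, and anti-correlation is not same-molecule evidence.

## Calibrating the grouping threshold

The grouping threshold is the correlation level at which all resonances of
a *known* compound — an internal standard such as DSS, or any metabolite
known to be present at high concentration and resonating at several
positions — are captured in a single group. `calibrate_threshold()` scans a
descending grid (0.95 to 0.30 by 0.05) and returns the largest value that
co-groups the reference clusters; `find_reference_clusters()` locates the
reference compound's spatial clusters from its library positions. The
calibrated value is data-dependent by design: overlap between multiplets
dilutes cluster representatives and lowers the correlation level at which
same-molecule clusters chain, and the reference compound experiences the
same dilution as everything else. When no reference is supplied the
default threshold is 0.8.

# Library matching

A library is a table of (metabolite, cluster, peak ppm) rows. A library
cluster counts as detected by a STOCSY group when at least one of its
reference peaks lies within ±0.025 ppm (the tolerance absorbing pH,
temperature and ionic-strength shifts) of a detected peak of that group;
peaks are detected on the mean spectrum by the same strict local-maximum
rule. Per metabolite, the detection ratio is the **maximum over groups** of
detected/total library clusters inside the 0.5–4.0 ppm scoring window —
per-group scoring preserves the same-molecule evidence STOCSY provides and
does not pool accidental matches across unrelated groups. Identification
requires the ratio to *strictly exceed* 0.55: a nine-cluster metabolite is
identified from five detected clusters ($5/9 \approx 0.556$), not four.

Single-cluster metabolites carry no cross-cluster evidence, so with the
*singlet filter* enabled (default) they are identified only from a
self-correlated group: either a singleton group, or a group whose every
member cluster matches that same resonance — the latter case covers a
multiplet split into adjacent fragments by an overlap, whose fragments'
mutual correlation must not disqualify the metabolite. Groups matching no
library cluster at all are reported verbatim as unannotated candidates:
they are the method's window onto compounds absent from the library.

# The spectrum simulator

The simulator exists so the whole pipeline can be exercised and scored with
no external data. Observed spectra follow

$$y_i(f) = S_i(f) + N_i(f), \qquad
  S = \left(H\Sigma + \mathbf{1}_n \alpha^{\mathsf T}\right) M ,$$

where $M$ ($L \times p$) holds per-metabolite reference spectra scaled to
maximum 1, $\alpha_l \sim \chi^2(\gamma)$ (drawn once per dataset: the
population mean concentrations, shared across samples) and
$H_{il} \sim N(0, \phi^2)$ (per-sample variation). The noise is a
stationary AR(1) sequence along the ppm axis with coefficient $\rho$
(default 0.9) and stationary SD `noise_sd`; the innovation SD is derived as
$\sigma\sqrt{1-\rho^2}$, so the marginal noise scale is directly
controllable. The empirical signal-to-noise ratio is the variance of the
signal entries over the variance of the noise entries
(`compute_snr()`).

## Synthetic reference spectra

Real reference libraries are instrument- and lab-specific, so
`build_reference_spectra()` synthesizes $M$: each metabolite resonates in
1–9 clusters (uniform; the 10-metabolite scenario then carries ~50
clusters, the density of complex metabolite spectra), each cluster a
singlet, doublet or 1:2:1 triplet (probabilities 0.40/0.35/0.25) of
Lorentzian lines at a random position, with within-multiplet spacing
drawn from 0.008–0.015 ppm (6–12 Hz at 800 MHz) and relative cluster
amplitudes from $U(0.3, 1)$. The default half-width at half-maximum is
0.0015 ppm — 1.2 Hz at 800 MHz, i.e. a realistic post-processing linewidth
for a modern high-field instrument; substantially broader lines make the
synthetic spectra overlap far more severely than real ones. The default
grid is $p = 3500$ uniform points over 0.5–4.0 ppm (0.001 ppm per point,
within the typical 3000–8000-point range of processed spectra).

Each row of $M$ is rescaled to maximum exactly 1, and the generator emits
both the ground-truth library of cluster peak positions (for matching) and
per-metabolite *true regions* — datapoints where the reference intensity
exceeds 1% of the row maximum. The 1% floor is needed because Lorentzian
tails are unbounded; coverage scoring requires a finite support.

## What the generator does and does not emulate

It emulates multiplet structure, chi-squared concentration laws, Gaussian
per-sample variation, metabolite–metabolite correlation (through $\Sigma$),
and serially correlated baseline noise. It does **not** model J-coupling
physics, pH-dependent shift drift, peak misalignment between samples, water
or solvent artifacts, or time-domain effects. Passing tests on simulated
data therefore demonstrate the statistical machinery — not robustness to
misalignment, which real preprocessing must provide upstream (the tool
assumes aligned, phased, baseline-corrected input).

# Preprocessing

Two conditioning steps are provided. Probabilistic quotient normalization
(`pqn_normalize()`) removes per-sample dilution: spectra are integral
normalized, a median reference spectrum is formed, and each spectrum is
divided by the median of its pointwise quotients against the reference
(quotients taken where the reference is positive). PQN is idempotent up to
numerical tolerance.

Baseline zeroing (`baseline_zero()`) sets every intensity below
$5 \times$ the SD of a user-chosen noise region to zero (SD pooled over all
samples for robustness at small $n$). On simulated data this stage is
*essential*, not cosmetic: AR(1) noise along the ppm axis makes adjacent
baseline columns correlate at $\rho$ across samples, so an unzeroed
baseline reads as a highly correlated region and the landscape saturates.
Zeroing converts baseline columns to zero variance, which the landscape
treats as no dependence.

# The SRV baseline

For comparison, the statistical-recoupling-of-variables clustering is
implemented: the landscape $L_j = \sqrt{\operatorname{var}(x_{\cdot j})
\operatorname{var}(x_{\cdot j+1})}$ (1/n variances), cluster boundaries at
its strict local minima (plateau minima cut at the midpoint), clusters with
fewer than 10 variables discarded, and neighbouring clusters aggregated
left-to-right into super-clusters while their representative intensities
(member means) correlate above 0.9, at most three clusters per
super-cluster. SRV segments the whole axis between minima, so it cannot
express "no cluster here" except through the size filter — which is exactly
why its noise coverage exceeds SPA's in the package's comparison tests.

# Evaluation

`score_coverage()` scores a clustering against simulation ground truth by
per-datapoint set arithmetic: the signal set is the union of all true
regions, the noise set its complement; true coverage (= TPR) is the percent
of signal points covered by clusters and noise coverage (= FPR) the percent
of noise points covered. `score_identification()` compares identified names
with the simulated metabolite set.

# Numerical and design choices

* **Degenerate inputs.** Zero-variance columns contribute 0 to landscape
  pairs; zero-variance cluster representatives get 0 off-diagonal STOCSY
  correlations with a warning; an empty library or group set yields an
  empty report, not an error; a flat SRV landscape yields one spanning
  cluster.
* **Ties.** Threshold selection breaks ties toward the smallest $\lambda$;
  plateau extrema take their midpoint; the first matching spatial cluster
  is taken when locating reference resonances.
* **Determinism.** Every stochastic step (simulation, fold splits) is
  seed-controlled; a fixed seed makes the whole pipeline bit-reproducible,
  and the chosen $k$, $\lambda$ and STOCSY threshold are recorded in the
  run's provenance.
* **Problem sizes.** The package's own test suite exercises the full
  10-metabolite scenario (50 samples × 3500 datapoints) in ~0.5 s per
  replicate, 20-replicate property checks for the coverage and grouping
  invariants, and a 20-replicate 50-metabolite comparison against SRV;
  brute-force oracle comparisons run on instances up to 50 variables where
  exhaustive enumeration is exact.

# Known limitations

* The landscape needs at least 3 samples and meaningful across-sample
  variation; technical replicates of a single composition defeat the
  covariance signal.
* The baseline rule is noise-scaled, so near-noiseless input is degenerate:
  with vanishing noise essentially nothing is zeroed, Lorentzian tails keep
  the landscape elevated between true clusters, and spatial clusters fuse.
  Detection quality on simulated data is accordingly *better* at realistic
  noise levels than in the zero-noise limit — an intentional property of
  thresholding the baseline at five noise SDs.
* Heavily overlapped regions (several multiplets interleaved within a few
  linewidths) can fuse into one spatial cluster whose mixed representative
  correlates strongly with none of its parent metabolites; the calibrated
  grouping threshold compensates only when the calibration reference is
  itself affected by comparable dilution. Metabolites with exactly two
  library clusters are the most brittle, since losing either one drops the
  detection ratio to 0.5, below the 0.55 bar.
* Identification is positional: concentrations are not estimated, and two
  metabolites with indistinguishable resonance sets within the tolerance
  cannot be told apart.

# A worked example

```{r example, eval = FALSE}
library(nmrspa)

cfg <- simulation_config(L = 10, n = 50, seed = 1)
ref <- build_reference_spectra(cfg)
sim <- simulate_spectra(cfg, ref)

res <- run_pipeline(
  sim$observed, ref$library,
  noise_region = c(0.5, 0.65),
  stocsy_threshold = "auto",
  reference_metabolite = "M01",   # a known multi-resonance compound
  seed = 1001)
res
score_identification(res$report, ref$metabolite_names)[1:3]
```
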