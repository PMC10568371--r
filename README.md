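# nmrspa

Automated, untargeted metabolite identification in one-dimensional ¹H-NMR
spectra, for metabolomics researchers who want library-level readouts from
a set of aligned spectra without operator-driven profiling.

A spectrum set (samples × chemical-shift datapoints) is analyzed in three
data-driven stages:

1. **Spatial clustering (SPA).** A moving-window *correlation landscape*
   scores each position by the average pairwise Pearson correlation of the
   next *k* spectral variables across samples,

   Q<sub>j</sub> = 2/(k(k−1)) · Σ<sub>a&lt;b</sub> ρ(x<sub>·j+a</sub>, x<sub>·j+b</sub>),

   is kernel-smoothed (tricube or Epanechnikov), and is thresholded at λ to
   yield contiguous clusters of datapoints belonging to one structural
   unit. The window *k* is selected from the partial autocorrelation
   function of the spectra; λ is selected by prediction-strength cluster
   stability with the one-standard-error rule.
2. **STOCSY grouping.** Cluster representative intensities (mean of local
   maxima per sample) are correlated across samples; connected components
   at a grouping threshold — calibrated as the level at which all
   resonances of an internal-standard/reference compound co-group, 0.8 by
   default — link clusters belonging to the same molecule.
3. **Library matching.** Groups are matched to a resonance library with a
   ±0.025 ppm tolerance; a metabolite is identified when its detection
   ratio (matched / total library clusters in 0.5–4 ppm) exceeds 0.55,
   with a singlet filter guarding single-cluster metabolites. Groups
   matching nothing are reported as unannotated candidates.

The package also ships the full simulation model used to validate the
method — Lorentzian multiplet reference spectra, χ²(γ) concentrations,
N(0, φ²) per-sample variation, stationary AR(1) noise — plus probabilistic
quotient normalization, noise-scaled baseline zeroing, an SRV
(statistical recoupling of variables) baseline clustering for comparison,
and coverage / identification scoring against simulation ground truth.

## Worked example

Simulate the 10-metabolite scenario (50 spectra, 3500 datapoints over
0.5–4.0 ppm, γ = 60, φ = 12, AR(1) noise with ρ = 0.9) and run the full
pipeline against the generator's own ground-truth library:

```r
library(nmrspa)

cfg <- simulation_config(L = 10, n = 50, seed = 1)
ref <- build_reference_spectra(cfg)
sim <- simulate_spectra(cfg, ref)

res <- run_pipeline(
  sim$observed, ref$library,
  noise_region = c(0.5, 0.65),      # signal-free margin for baseline zeroing
  stocsy_threshold = "auto",        # calibrate on a reference compound
  reference_metabolite = "M01",     # 9 library clusters: the DSS analogue
  seed = 1001)
res
#> <nmrspa_pipeline> k=6 lambda=0.55 stocsy=0.35: 30 clusters -> 3 groups
#> <identification_report> 10/10 metabolites identified, 0 unannotated candidate group(s)

score_identification(res$report, ref$metabolite_names)[1:3]
#> $n_correct
#> [1] 10
#> $n_missed
#> [1] 0
#> $n_false
#> [1] 0

head(res$report$report, 3)
#>   metabolite n_library_clusters n_detected_clusters detection_ratio identified
#> 1        M01                  9                   6       0.6666667       TRUE
#> 2        M02                  3                   3       1.0000000       TRUE
#> 3        M03                  6                   6       1.0000000       TRUE
```

Reading the output: the PACF chose a 6-point window, prediction strength
chose λ = 0.55, and the STOCSY threshold calibrated at 0.35 on the
reference compound's resonances; 30 spatial clusters were found and
grouped, and every simulated metabolite exceeded the 0.55 detection
ratio (e.g. M01: 6 of its 9 library clusters matched by one group).

A thin command-line front end over the same functions is installed at
`inst/scripts/nmrspa`:

```sh
Rscript inst/scripts/nmrspa simulate --L 10 --n 50 --seed 1 --out-dir sim
Rscript inst/scripts/nmrspa run --input sim/spectra.csv --library sim/library.csv \
    --noise-region 0.5,0.65 --stocsy-threshold auto --reference-metabolite M01 \
    --seed 1 --out-dir results
```

See `vignettes/spa-stocsy-methods.Rmd` for the model, parameter defaults
and design rationale.

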