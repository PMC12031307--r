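# bisfruit

Equivalent-circuit modelling of whole-fruit bioimpedance spectra and a
repeated cross-validation benchmark for classifying how the fruit was
stored.

## The problem

Bioelectrical impedance spectroscopy (BIS) measures a fruit's complex
impedance `Z(f) = Z' + jZ''` over a frequency sweep (here 30 log-spaced
points from 50 Hz to 1 MHz). Storage at room temperature dries the fruit:
extracellular and intracellular resistances rise and membrane capacitance
falls, which shifts the low-frequency impedance and the phase spectrum,
while cold storage leaves the spectrum nearly unchanged. Those changes are
small relative to fruit-to-fruit variation, so per-fruit *time-delta*
features (each measurement minus that fruit's own day-0 baseline) and the
fruit's diameter are the key to a reliable classifier.

`bisfruit` provides the full analysis chain for this setting, aimed at
postharvest and biosensing researchers:

* a forward model for the modified Hayden equivalent circuit with
  constant-phase elements (CPE),

      Z(ω) = [R_e ∥ Z_CPE,e(ω)] + [R_ex ∥ (R_i + Z_CPE,m(ω))],
      Z_CPE = 1 / (Q (jω)^α),

  giving seven free parameters `(R_e, Q_e, α_e, R_ex, R_i, Q_m, α_m)`;
* `fit_ec()`, a bounded multi-start complex nonlinear least-squares fitter
  returning a classed model object (`coef`, `predict`, `plot`, `residuals`,
  `summary` methods), with the EIS chi-square statistic
  `χ² = (1/2N) Σ [((Z'-Ẑ')/|Z|)² + ((Z''-Ẑ'')/|Z|)²]`
  and the conventional quality gate `χ² ≤ 3×10⁻⁴`;
* a seeded synthetic cohort generator (`simulate_cohort()`) emulating the
  reference study design — 184 fruit in a balanced 2 size × 2 storage
  layout, measured on days 0/1/2, 552 spectra — with size-coupled membrane
  capacitance, storage-dependent parameter drift and measurement noise;
* assembly of the six benchmark datasets (`assemble_dataset()`): raw
  bioimpedance (368×60), bioimpedance deltas (368×60), deltas + diameter
  (368×61), and the circuit-parameter analogues (368×7, 368×7, 368×8);
* `run_benchmark()`: eight classifier families (SVM, logistic regression,
  MLP, kNN, random forest, LDA, naive Bayes, decision tree) tuned by grid
  search under 5×-repeated stratified 10-fold CV with one shared fold
  pairing, compared per family with paired Wilcoxon signed-rank tests and
  compact significance letters, plus held-out confusion-matrix metrics.

## Worked example

Fit the circuit to a noisy spectrum, then benchmark a small cohort:

```r
library(bisfruit)
set.seed(1)
truth <- ec_params(r_e = 320, q_e = 1.2e-5, alpha_e = 0.86,
                   r_ex = 2800, r_i = 950, q_m = 6e-8, alpha_m = 0.81)
spec  <- simulate_spectrum(truth)
pol   <- to_polar(complex(real = spec$z_real, imaginary = spec$z_img))
noisy <- impedance_spectrum(spec$freq,
           from_polar(pol$magnitude * (1 + rnorm(30, 0, 0.005)),
                      pol$phase_deg + rnorm(30, 0, 0.5)))
fit_ec(noisy, seed = 1)
#> Equivalent-circuit fit (parallel_electrode)
#>       r_e       q_e   alpha_e      r_ex       r_i       q_m   alpha_m
#> 2.637e+02 6.760e-06 9.966e-01 2.840e+03 9.448e+02 6.525e-08 8.035e-01
#> chi-square 3.58e-05 (passes gate 0.0003), start 8 of 8, converged
```

The tissue parameters `r_ex`, `r_i`, `q_m`, `alpha_m` are recovered within
a few percent at this noise level (0.5 % magnitude, 0.5° phase) and the fit
passes the `3×10⁻⁴` chi-square gate. The electrode block is flatter in the
measured band, so its parameters absorb more of the noise — that, and an
exact two-fold labelling ambiguity of this circuit, are discussed in the
methods vignette (`vignettes/bisfruit-methods.Rmd`).

```r
ch <- simulate_cohort(seed = 1, design = study_design(n_per_group = 10))
kinds <- c("bio-raw", "bio-delta", "bio-delta-diam")
ds <- setNames(lapply(kinds, function(k) assemble_dataset(ch, k)), kinds)
run_benchmark(ds, families = c("svm", "lda", "knn"), seed = 1,
              grids = list(svm = expand.grid(cost = c(1, 10),
                                             kernel = c("linear", "radial"),
                                             gamma = "scale",
                                             stringsAsFactors = FALSE)))
#> BIS classifier benchmark: 3 datasets x 3 families, 5x10-fold CV
#>   bio-raw          SVM 0.78^a(0.17)  LDA 0.51^a(0.22)  KNN 0.75^a(0.16)
#>   bio-delta        SVM 1.00^b(0.00)  LDA 0.71^b(0.22)  KNN 0.98^b(0.05)
#>   bio-delta-diam   SVM 1.00^b(0.00)  LDA 0.67^b(0.25)  KNN 0.98^b(0.05)
```

Each cell is the mean (sd) CV accuracy of the tuned model; superscript
letters compare the three datasets within a model column — datasets sharing
a letter are not significantly different under the paired signed-rank test
at p < 0.05. Even at this reduced cohort size the delta datasets separate
the storage groups far better than the raw spectra. At the full design
size (46 fruit per cell) the raw-spectrum SVM sits in an intermediate
accuracy regime (~0.70) and the delta and delta+diameter datasets reach
~0.96, with the ordering raw ≤ delta ≤ delta+diameter.

`run_pipeline()` ties all stages together (simulate → fit → assemble ×6 →
benchmark → report) from a YAML config and writes CSV/JSON outputs plus a
run manifest; see `inst/extdata/example-config.yaml`.

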