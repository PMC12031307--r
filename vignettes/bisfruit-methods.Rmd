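---
title: "Methods: circuit model, synthetic cohorts and the classifier benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit model, synthetic cohorts and the classifier benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`bisfruit`: the equivalent-circuit model and its identifiability, the
fitter, what the synthetic cohort generator emulates (and does not), how
the feature datasets are assembled, and how the classifier benchmark is
constructed so that its paired statistics are valid.

## 1. The equivalent circuit

A fruit measured between two surface electrodes is modelled as an
electrode interface block in series with the classic Hayden tissue block:

$$Z(\omega) = \underbrace{R_e \parallel Z_{CPE,e}(\omega)}_{\text{electrode}}
            + \underbrace{R_{ex} \parallel \big(R_i + Z_{CPE,m}(\omega)\big)}_{\text{tissue}},
\qquad Z_{CPE} = \frac{1}{Q\,(j\omega)^\alpha},$$

where $a \parallel b = ab/(a+b)$ over complex values. $R_{ex}$ and $R_i$
are the extracellular and intracellular fluid resistances; the cell
membrane is a constant-phase element (CPE) rather than an ideal capacitor
because distributed tissue heterogeneity produces a depressed dispersion
($\alpha < 1$; $\alpha = 1$ recovers an ideal capacitor, $\alpha = 0$ a
resistor $1/Q$). The electrode contact is likewise a resistance shunted by
a CPE, the standard lumped model of electrode polarisation. Seven scalar
parameters result: $R_e, Q_e, \alpha_e, R_{ex}, R_i, Q_m, \alpha_m$.

The exact wiring of the electrode interface is a modelling choice;
`circuit_impedance()` exposes it as a `topology` switch
(`parallel_electrode`, the default and the physically standard form, or
`series_electrode`). All user-facing interfaces use frequency in Hz;
$\omega = 2\pi f$ is internal. Phases are reported in degrees with the
quadrant-correct arctangent, so capacitive behaviour is negative and a
lone CPE has phase exactly $-90\alpha$ degrees.

### Identifiability: an exact two-fold ambiguity

Writing $s = j\omega$, the total impedance factors as

$$Z(s) = C + \frac{A_1}{1+\tau_1 s^{\alpha_1}} + \frac{A_2}{1+\tau_2 s^{\alpha_2}},$$

with $A_1 = R_e$, $\tau_1 = R_e Q_e$, $C = R_{ex}R_i/(R_{ex}+R_i)$,
$A_2 = R_{ex}^2/(R_{ex}+R_i)$ and $\tau_2 = (R_{ex}+R_i)Q_m$. The two
dispersion terms are interchangeable: *either* can be realised by the
electrode block, with the constant $C$ re-absorbed into the tissue block.
Consequently two distinct parameter vectors generate *identical* spectra —
we observed noiseless fits landing on the alternate solution with
$\chi^2 \approx 10^{-32}$. The map between the two labellings is closed
form, and `canonicalize_ec()` resolves the ambiguity by the physical
convention that electrode polarisation is the slower process: the
dispersion with the lower characteristic frequency
$\omega_c = \tau^{-1/\alpha}$ is assigned to the electrode block.
`fit_ec()` canonicalises its result by default (whenever no non-exchangeable
parameter is held fixed), and all recovery statements in the test suite are
made on canonical labellings. Users fitting tissues where the electrode
dispersion genuinely sits *above* the membrane dispersion should disable
`canonical` and rely on informative starting values instead.

## 2. Fitting

`fit_ec()` minimises the modulus-weighted residuals
$\big(Z'-\hat Z'\big)/|Z|$ and $\big(Z''-\hat Z''\big)/|Z|$ at every
frequency with the Levenberg–Marquardt algorithm (`minpack.lm`). The
associated fit statistic is

$$\chi^2 = \frac{1}{2N}\sum_{k=1}^{N}\left[
  \left(\frac{Z'_k-\hat Z'_k}{|Z_k|}\right)^2 +
  \left(\frac{Z''_k-\hat Z''_k}{|Z_k|}\right)^2\right],$$

i.e. the mean squared *relative* complex deviation. Weighting by $|Z|$ is
essential because magnitudes span orders of magnitude between 50 Hz and
1 MHz; the $1/2N$ normalisation makes the statistic comparable across
spectra. Fits with $\chi^2 \le 3\times 10^{-4}$ are treated as accurate;
because weighting conventions differ between implementations, that gate is
calibrated to *this* definition (at the default measurement noise of 0.5 %
magnitude and 0.5° phase, typical converged fits land near
$\chi^2 \approx 5\times10^{-5}$, comfortably inside the gate).

Numerical choices:

* **Parameterisation.** Resistances and CPE magnitudes are optimised in
  log space, ideality factors in logit space. This enforces $R, Q > 0$ and
  $\alpha \in [0,1]$ smoothly, equalises scales, and needs no constrained
  solver. Exact boundary values ($\alpha = 1$) are handled by fixing
  parameters (`fixed = c(alpha_e = 1, alpha_m = 1)` gives the reduced
  ideal-capacitor fit).
* **Multi-start.** Least-squares fits of this circuit depend on the start.
  The default 8 starts are deterministic: a data-driven heuristic (DC and
  high-frequency plateaus give $R_e + R_{ex}$ and $R_{ex}\parallel R_i$;
  the phase extremum locates the membrane relaxation and hence $Q_m$;
  $\alpha$ starts at 0.8), its exact block-swapped mirror (covering the
  other labelling basin), and seeded log-uniform jitters around both. The
  lowest-$\chi^2$ converged start wins, lowest index on ties, so the result
  does not depend on start order.
* **Tolerances.** Relative cost and step tolerances $10^{-10}$, at most
  2000 residual evaluations and 1024 iterations per start. Noiseless
  recovery over 50 random cohort-like truths is exact to
  $\sim 10^{-13}$ relative.

## 3. The synthetic cohort generator

No public measurement data exist for this design, so the generator is a
first-class, tested component: it emulates the *structure* of a two-size,
two-storage mandarin study so every downstream stage is exercised under
realistic conditions.

* **Design.** 46 fruit per size × storage cell (184 fruit), measured on
  days 0/1/2: 552 spectra, of which the 184 day-0 spectra are only
  baselines, leaving 368 instances. Storage labels are assigned *after*
  all baseline quantities are drawn, so day-0 distributions are
  exchangeable across storage groups by construction.
* **Diameters.** Small fruit $\sim\mathcal N(55, 3^2)$ mm, large
  $\sim\mathcal N(70, 3^2)$ mm — two clearly separated distributions. The
  means are placeholders for an unpublished sizing; they are config values
  (`cohort_params()`), not constants.
* **Baselines.** Circuit parameters are log-normal with medians
  $R_e = 300\,\Omega$, $Q_e = 10^{-5}$, $R_{ex} = 3\,\mathrm{k}\Omega$,
  $R_i = 1\,\mathrm{k}\Omega$, $Q_m = 5\times10^{-8}$ and log-sds
  0.25–0.4; ideality factors are truncated normal around 0.85/0.80. These
  put the electrode dispersion near ~150 Hz and the membrane dispersion
  near ~5 kHz — about 1.5 decades apart, so the canonical labelling is
  stable across the cohort — and give kΩ-scale spectra typical of
  whole-fruit surface measurements.
* **Size coupling.** Membrane capacitance scales with membrane area, so
  $Q_m \propto (d/d_{ref})^{2}$ with $d_{ref} = 62.5$ mm. Note the phase
  consequence is band-dependent: raising $Q_m$ *lowers* the membrane
  relaxation frequency, so large fruit show *larger* $|\theta|$ below the
  relaxation and *smaller* $|\theta|$ above it (where the reactance
  argument $1/\omega Q$ applies). The frozen seeded test checks the
  above-relaxation band (~46 kHz). The coupling sign and exponent are
  config values.
* **Drift.** Room storage multiplies $R_{ex}$ by 1.12, $R_i$ by 1.08 and
  $Q_m$ by 0.85 per day (water loss: shrinking membrane area, rising fluid
  resistances), compounding across days, modulated by
  $(d_{ref}/d)^{2}$ — smaller fruit dry relatively faster
  (surface-to-volume) — and jittered per fruit per day (log-sd 0.08).
  Cold storage applies only a small jitter (log-sd 0.035); with the jitter
  at 0, cold-group parameters are *exactly* constant, which anchors the
  delta-feature tests. The magnitudes were fixed by a three-seed sweep so
  that a tuned SVM on raw day-1/2 spectra attains an intermediate (~0.7)
  CV accuracy — neither trivial nor impossible — while delta features
  separate the groups much more cleanly (~0.96); they live in
  `cohort_params()`, not in code.
* **Noise.** Multiplicative magnitude noise (sd 0.5 %) and additive phase
  noise (sd 0.5°) per frequency point.

What the generator does **not** model: purchase-batch effects (an optional
offset exists but is off by default), humidity and re-warming protocols,
chilling injury, electrode drying/repositioning drift, and any mechanistic
water-transport dynamics. Passing tests therefore demonstrate that the
pipeline is correct and that the *structural* premises (delta features
cancel baseline variation; diameter explains part of the drift variance)
are realised — not that real mandarins behave quantitatively like the
defaults.

## 4. Feature datasets

Six datasets pair two feature families with three variants. Bioimpedance
features are the 30 magnitudes then the 30 phases in ascending frequency;
circuit features are the seven parameters in the order
`r_e, q_e, alpha_e, r_ex, r_i, q_m, alpha_m`; the diameter, when included,
is the last column. Deltas are $\Delta X_t = X_t - X_0$ with
$t \in \{24, 48\}$ h mapping to days 1 and 2; day-0 rows are consumed,
never emitted. Deltas are computed on raw values *before* any
normalisation — the only order that keeps the zero-drift cold group
centred at exactly zero (a flag provides the reverse order). The diameter
is a day-0 constant per fruit, as re-measuring it daily is not part of the
emulated protocol.

Normalisation is z-scoring per feature with the *population* sd
(divide by $n$; configurable). By default the statistics are fitted on
training data only — inside each CV fold during selection, on the full
training split for the held-out evaluation — so no information leaks from
evaluation rows. A `paper_mode` switch instead normalises the full table
before splitting, replicating the common normalise-then-split practice for
comparison. The 8:2 split is stratified by storage with the train size
rounded half-up per stratum (368 → 294/74).

## 5. The classifier benchmark

Eight families are tuned by grid search under 5×-repeated stratified
10-fold CV. One fold-assignment matrix, derived from the master seed, is
shared by **every** grid point, family and dataset in a run; this identical
pairing is the precondition for comparing datasets with a *paired* test,
and `fold_signature()` lets callers assert it. Selection functions receive
only the training table, so held-out rows cannot influence tuning (the
suite verifies that corrupting test rows changes nothing upstream).

Default grids are small and conventional: SVM `C ∈ {0.1,1,10,100}` ×
{linear, RBF with γ ∈ {scale, 0.01, 0.001}}; ridge-logistic `C ∈
{0.01,0.1,1,10}` (λ = 1/(nC)); MLP one hidden layer of {4, 8, 16} units
with weight decay {1e-4, 1e-3} — sized to the ~300-instance, ≤61-feature
problems here, where larger layers only add variance and run time; kNN
`k ∈ {3,…,11}`; random forest {100, 300} trees × max depth {∞, 5, 10};
LDA and Gaussian NB without grids; decision tree max depth {∞, 3, 5, 10}.
All grids are arguments, not constants.

Dataset comparisons use the two-sided Wilcoxon signed-rank test on the 50
paired per-fold accuracies. Zero differences are discarded (Wilcoxon's
original convention); the exact distribution is used when ≤ 25 nonzero,
untied differences remain, otherwise the normal approximation with
continuity correction; identical vectors give p = 1 by convention. Compact
letters are assigned per model family within each feature group
(bioimpedance, circuit) from the maximal cliques of the
not-significantly-different graph, lettered in dataset row order;
intransitive patterns produce overlapping letters and a warning. No
multiple-testing correction is applied across the three pairwise
comparisons (a Holm option exists at the `assign_letters` level via its
p-matrix input). Confusion-matrix metrics use "room" as the positive class
by default and are reported for both classes; an undefined precision
(no positive predictions) is returned as `NA`, not 0.

## 6. Problem sizes and the ordering battery

The multi-seed ordering check (`ordering_battery()`) re-simulates a
default-scale cohort per seed and asks whether the tuned SVM's mean CV
accuracy is non-decreasing from raw to delta to delta+diameter features,
counting a decrease within one sd of the earlier dataset's accuracy
distribution as a tie. The battery tunes over a condensed SVM grid
(`C ∈ {1, 10}` × {linear, RBF-scale}) — at battery scale the larger
default grid selects the same kernels and changes mean accuracies by well
under one sd, so the condensed grid is the package's chosen
accuracy/run-time trade-off for repeated simulation studies. Unit tests
exercise reduced cohorts (2–8 fruit per cell) for speed; the acceptance
script runs the full 184-fruit design.

## 7. Known limitations

* The circuit is a lumped, isotropic model; series inductance, multiple
  tissue compartments and electrode geometry effects are out of scope, as
  is automatic circuit-topology selection and Kramers–Kronig validation.
* The chi-square gate is meaningful only under this package's weighting
  convention; gates from other software are not directly transferable.
* Synthetic cohorts demonstrate pipeline correctness, not mandarin
  physiology; all generator constants are explicit configuration with the
  defaults documented above.
* With `paper_mode = TRUE` the reported CV accuracies inherit the mild
  optimism of normalising before splitting; the default avoids it.
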