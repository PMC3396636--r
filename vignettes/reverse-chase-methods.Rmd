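---
title: "Growth-corrected mRNA half-lives from transcriptional chase data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-corrected mRNA half-lives from transcriptional chase data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rechase)
```

## The measurement problem

Tet-conditional ("Tet-Off") chase experiments estimate an mRNA's stability by
silencing its TRE-linked gene with doxycycline and following the decline of
the transcript, quantitated by RT-qPCR relative to an antibiotic-indifferent
control mRNA such as β-actin. The complication is that the culture keeps
growing while the study gene is silent. The study-mRNA pool is fixed at
shutoff and decays; the control-mRNA pool grows with cell number. The
normalized ratio therefore declines even for a perfectly stable transcript,
and in general decays with constant

$$k_\mathrm{observed} = k_\mathrm{true} + j,$$

where $j$ is the exponential expansion constant of the culture
($C(t) = C_0 e^{jt}$). Uncorrected, an infinitely stable mRNA appears to have
a half-life equal to the culture doubling time $\ln 2 / j$; more generally
the apparent and true half-lives obey the harmonic identity
$1/t_\mathrm{app} = 1/t_\mathrm{true} + 1/t_\mathrm{double}$
(`apparent_half_life()`).

Two corrections are algebraically equivalent and both are implemented:

* **Conventional design** — every aliquot gets dox at $t=0$ and is sacrificed
  at its chase time with a cell count. Each normalized quantity is multiplied
  by $C_t/C_0$ (`correct_conventional()`); the corrected series decays with
  $k_\mathrm{true}$ and the half-life is $\ln 2 / k$.
* **Reverse chase** — aliquots get dox at staggered times and are all
  sacrificed together, so every aliquot holds the same number of cells and no
  counting is needed. The raw normalized series is fitted and the half-life is
  $\ln 2 / (k - j)$, with $j$ measured once per culture from a cell-count
  series (`fit_expansion()`).

The reverse chase trades per-aliquot counting (minutes of handling per
timepoint, and a 5–10% counting error each time) for a single growth-curve
measurement, which is why it supports far denser sampling at equal effort.

## Quantitation: ΔΔCt with outlier censoring

`delta_delta_ct()` implements standard relative quantitation: per aliquot,
$\Delta Ct = \overline{Ct}_\mathrm{study} - \overline{Ct}_\mathrm{control}$;
against the calibrator aliquot (the shortest chase time, normally 0),
$\Delta\Delta Ct$ and $q = E^{-\Delta\Delta Ct}$. The amplification
efficiency $E$ defaults to 2.0 per cycle, the textbook assumption; it is a
single scalar argument because no per-target efficiencies are available in a
typical multiplexed Taqman setup, and no inter-target efficiency correction
is attempted. When several aliquots sit at the calibrator time their mean
$\Delta Ct$ anchors the scale.

Technical triplicates are censored before averaging (`censor_ct()`): the
value farthest from the median is dropped iff it deviates from the median of
the remaining values by more than 0.5 cycles. The threshold is a package
choice (instrument vendors use a proprietary rule); 0.5 cycles is roughly a
1.4-fold quantity discrepancy, far beyond well-to-well pipetting noise. At
most one value is ever dropped, pairs are never censored, and the rule is
idempotent. Aliquots left with fewer than two study or control replicates are
excluded with a warning — never imputed. Undetected wells are missing values,
never sentinel Cts.

## Growth: fitting the expansion constant

`fit_expansion()` regresses $\ln(\mathrm{count})$ on time by OLS. The log
scale is the variance-stabilizing choice for counts spanning orders of
magnitude, and makes the estimator deterministic; a nonlinear option is
deliberately not offered. The 95% CI on $j$ is the usual t-interval on the
slope ($df = n-2$). `compare_conditions()` fits dox-supplemented and dox-free
series separately and reports whether the CIs overlap — the design's
assumption that growth is indifferent to the antibiotic. Counts may be
non-integer (hemocytometer means). Chase windows are treated as
exponential-phase only; saturating growth is out of scope.

`convert_rate()` moves $j$ between per-minute and per-hour exactly (factor
60), with an optional 4-decimal rounded view matching common reporting.

## Decay fitting

`fit_decay()` offers two methods:

* `log_linear` (default): OLS of $\ln q$ on time. Deterministic, no starting
  values, exact on single-exponential data. $R^2$ is reported on the log
  scale.
* `nonlinear`: damped least squares (Levenberg–Marquardt, via minpack.lm) of
  $q(t) = p + (n_0 - p)e^{-kt}$ on the linear scale, initialized from the
  log-linear fit with plateau start $\min(q)/2$. Required for the plateau
  term $p$, which models background dox-indifferent transcription: a residual
  synthesis floor that a plain exponential misses, biasing $k$ low at late
  times. $R^2$ is reported on the linear scale. The `scale_of_r2` field makes
  the scale explicit, because an $R^2$ without its scale is not comparable
  across methods.

Numerical choices: a negative fitted plateau (possible on super-exponential
data) is clamped — the model is refit with $p = 0$ and flagged rather than
reported; non-convergence within the iteration cap raises an error carrying
the last iterate; duplicate chase times are treated as replicates; fits are
unweighted. Degenerate inputs fail loudly: fewer than 3 points (4 with
plateau), non-positive quantities, and $k \le j$ at the half-life step — the
latter means the transcript appears infinitely stable or accumulating at the
experiment's precision, and the package refuses to print a negative or
infinite half-life silently.

The plateau model is fitted to quantities that are otherwise fully corrected
for growth. When growth dilution is present the observed profile is
$e^{-jd}[p + (1-p)e^{-k d}]$, which is *not* of plateau-plus-exponential
form; the bundled `plateau_demo` scenario therefore uses a growth-arrested
culture ($j = 0$), and plateau fitting on growing cultures should be applied
to conventionally corrected data.

## The simulator

`simulate_chase()` generates both designs from one mechanistic model: cells
grow as $C(t) = C_\mathrm{seed}e^{jt}$ regardless of dox; the control signal
is proportional to cell number at sacrifice; the study signal is proportional
to cell number at shutoff times
$p + (1-p)e^{-k_\mathrm{true}d}$ for chase duration $d$; Ct values are
back-computed as $ref - \log_2(\mathrm{signal})$ plus Gaussian noise per
technical replicate. Under this model the noiseless normalized quantity is
$e^{-(k_\mathrm{true}+j)d}$ in **both** designs — the algebra the two
corrections undo — which the test suite verifies exactly, along with the
equivalence of the two full pipelines on noiseless data.

Noise defaults are package choices (the underlying study quantifies none):

* `ct_sd = 0.15` cycles — typical well-to-well repeatability of a plate
  instrument;
* `count_cv = 0.10` — hemocytometer counting error, multiplicative
  (lognormal) because it scales with magnitude; conventional design only;
* `seeding_cv = 0.02` — variation in cells seeded per aliquot. Seeding error
  cancels in the normalized ratio (both signals share the aliquot's cells)
  but corrupts the conventional correction through the count ratio.

All magnitudes are arguments, simulations are bit-reproducible given the
seed, and Monte-Carlo child seeds derive from the master seed by a
`sample.int()` draw so individual runs reproduce in isolation. Biological
replicates are independent noise draws from the same truth; the model has no
between-replicate biology, no shutoff lag (silencing is assumed complete and
instantaneous, so the dox refresh at mid-chase is a no-op), no cell-cycle
structure, and no RT-efficiency variation between genes. Passing tests
therefore validate the estimator against this idealized generative model,
not against organism-level variability: real conventional chases are
typically *worse* than simulated ones, because iterative handling adds
variability beyond the counting error modeled here.

## Design comparison and what it can and cannot show

`compare_designs()` runs both designs through the full
quantitation-plus-estimation pipeline over many seeds and summarizes
half-life precision and fit reliability. With the sampling densities used in
the test suite — a short chase (true $t_{1/2}$ = 20 min, reverse chase at
5-min spacing for 21 points vs conventional 30-min spacing for 4 points) and
a long chase (true $t_{1/2}$ = 32 h, 21 vs 7 points over 80 h), 200
simulations each at default noise — the reverse-chase estimator's median
absolute error stays under 10% of truth and its SD is strictly below the
conventional SD in both scenarios.

The $R^2$ contrast needs more care. In the long chase, counting error visibly
scatters the sparse conventional fit and mean reverse-chase $R^2$ exceeds
conventional $R^2$. In the short chase, log-scale $R^2$ saturates above 0.99
for *both* designs: the signal traverses a large dynamic range quickly, the
counting error is small against it, and a 4-point fit overfits $R^2$ upward —
so the statistic does not discriminate there, and the suite asserts the
contrast only where the model predicts it robustly. Relatedly, when both
designs share identical timepoints and the only noise is Ct noise, they are
statistically identical under this model (a property test documents this):
the reverse chase's advantage is driven by eliminating counting/handling
error and by the denser sampling it makes affordable, not by the qPCR step.
Published real-data reliability gaps are larger than the simulated ones,
consistent with handling variability that this model deliberately omits.

## Problem sizes

Simulated experiments are small by design — at most 21 aliquots × 2 genes ×
3 technical replicates — and the Monte-Carlo blocks use 200 seeds per
scenario, sizes at which every distributional claim in the test suite is
stable across master seeds while the whole suite runs in a couple of
minutes. The acceptance script's scenario (5 timepoints, zero noise) is
deterministic.

## Limitations

* Single-exponential (plus optional plateau) decay only; biphasic decay is
  out of scope, as are bootstrap CIs on the half-life.
* The ΔΔCt step assumes a common amplification efficiency for study and
  control targets.
* $j$ is assumed constant over the chase window (exponential phase);
  growth-arrested or saturating cultures need $j$ measured over the actual
  window.
* The simulator's noise magnitudes are plausible defaults, not measured
  instrument characteristics; conclusions that depend on their exact values
  should be re-run with study-specific estimates.
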