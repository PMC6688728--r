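---
title: "Evaluating sliding-window dynamic connectivity against a known ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sliding-window dynamic connectivity against a known ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sliding-window estimates of functional connectivity are the workhorse of
dynamic-connectivity analysis in MEG and EEG, yet the window length is an
arbitrary choice and empirical data offer no ground truth to validate it
against. `dfcsim` builds that ground truth synthetically: coupled neural
signals are simulated with a *known*, piecewise-constant coupling timecourse,
five conventional connectivity metrics are computed over 50%-overlapping
sliding windows, and the estimates are scored against the truth. Everything
in the package exists to answer two questions: when the underlying coupling
genuinely fluctuates, which metric/window combinations can tell, and how well
do they recover the actual timecourse?

## Ground-truth states

Hidden states switch with Gamma-distributed lifetimes
(`state_regime()`, `sample_lifetimes()`). The regimes are *fast*
(mean 125 ms), *medium* (1 s), *slow* (3 s) and *mixed* (each lifetime drawn
from one of the three with equal probability). The Gamma mean is the regime's
defining quantity; the shape parameter is not pinned down by the lifetime
means alone, so we default to `shape = 2` — unimodal, positively skewed
lifetimes, the qualitative shape expected of state dwell times — and expose
it in the constructor. The final lifetime is truncated (not resampled) so the
sequence sums exactly to the requested duration; at 300 s this biases the
pooled mean by well under 1% even for slow states.

Segment labels are drawn uniformly from all states *except* the previous one:
a self-transition would be an invisible "state change", so excluding it makes
every boundary a genuine change point. Coupling levels default to
low/medium/high = 0.3/0.6/0.9, spanning the admissible coupling range with
equal spacing; the static control condition holds the medium level
throughout.

## The two-node MAR model

Each state is an order-2 multivariate autoregressive process specified
through the eigenstructure of its 4x4 companion matrix
(`eigen_mar_spec()`, `eigen_to_mar()`): a complex-conjugate pole pair of
modulus `magnitude` (default 0.9) at `frequency` (default 20 Hz, the centre
of the 15–25 Hz analysis band) whose eigenvector loads the two nodes with
moduli `(weight_node1, weight_node2)` and relative phase `phase_lag`
(default pi/4 — non-zero so lag-sensitive metrics see the coupling, and away
from pi/2 so zero-lag-sensitive metrics do too). The node-2 weight *is* the
coupling strength; only it changes across states. Realizations are generated
by filtering white unit-variance Gaussian noise through the state-dependent
coefficients, switching matrices instantly at state boundaries while keeping
the running samples as history, so no transients are inserted.

The remaining ("inert") companion eigenvalues are a design choice the
eigen-parameters leave open. Placing them at zero makes the resonant mode's
innovation drive orthogonal to the conjugate mode shape, and the band-averaged
coherence then *decreases* as the node-2 weight grows — the opposite of the
intended behaviour. We instead place the inert pair at the same frequency
with modulus `inert_ratio * magnitude` (default 0.8) and mode shape `(0, 1)`:
a private resonance of node 2. Node 2's signal is then a mixture of the
shared mode (weighted by the coupling) and its own resonant floor, and the
parametric band coherence rises strictly monotonically from exactly 0 at
zero weight — the property the whole evaluation relies on. With the default
levels the parametric band coherences are roughly 0.35/0.60/0.74.

Two consequences worth knowing: the construction is exact (the companion
matrix is assembled from eigenvectors in companion form, so the eigendecomposition
round-trips to machine precision), and stability is automatic because every
eigenvalue has modulus below 1.

## The Jansen-Rit models

`jansen_rit_params()` carries the canonical published parameter set
(He = 3.25 mV, Hi = 22 mV, a = 100/s, b = 50/s, C1 = 135, C2 = 0.8 C1,
C3 = C4 = 0.25 C1, e0 = 2.5/s, v0 = 6 mV, r = 0.56/mV). The drive is the one
quantity we had to calibrate: `drive_mean = 220`/s puts the uncoupled unit
well past the lower Hopf bifurcation (numerically bracketed near 90/s by the
test suite) and inside the limit cycle, with an output spectrum peaking
around 10 Hz; `drive_sd = 8`/s adds enough stochasticity for realistic
variability without kicking the unit out of the alpha regime (stronger noise
visibly drags spectral power below 8 Hz). Integration uses the stochastic
Heun predictor-corrector at `dt = 1e-4` s with the Wiener increment entering
the excitatory-input equation and shared between predictor and corrector;
with zero noise this is the deterministic second-order Heun scheme (verified
by a Richardson convergence test).

For the two-node system the coupling is a time series: the ground-truth
level scaled by `k_scale` (default 40, chosen so that the windowed PLV spans
roughly 0.2 to 0.8 over coupling levels 0 to 0.9) multiplies the sigmoid of
the other node's pyramidal potential inside the excitatory drive.

The network model simulates N delayed Jansen-Rit units. Delays are Euclidean
centroid distances divided by a 10 m/s conduction velocity, rounded to
integer multiples of `dt` and served from a ring buffer of sigmoid-transformed
outputs initialized at the algebraic fixed point. The structural connectivity
tensor activates exactly one resting-state network at a time (all pairs
inside the active mask at weight 1, everything else 0); it is stored
run-length-compressed by state segment, with `structural_slice()` providing
the per-sample view. The global coupling `k = 6` was calibrated once so that
an active 8–12-node subnetwork's summed input keeps its members *inside* the
oscillatory regime: at roughly twice that coupling the active network is
pushed past the upper Hopf point, its alpha rhythm collapses, and
phase-locking contrasts vanish. Output is the pyramidal potential,
anti-alias filtered by a block average over the decimation factor (the
model's spectrum falls steeply above the alpha band, and the zero-phase
band-pass applied before any metric removes what little out-of-band content
survives) and decimated to 250 Hz. The first `max(1 s, max delay)` is
discarded as burn-in.

The packaged 78-region layout and DMN/SMN/FPN/visual masks are *synthetic*:
39 regions per hemisphere on an ellipsoidal cortical shell with masks placed
at anatomically plausible positions (occipital visual, central sensorimotor,
medial frontal + posterior midline + angular default mode, lateral
frontoparietal). They exercise the same machinery as empirically derived
templates but should not be used to draw anatomical conclusions; any CSV
with the same columns can replace them.

## Connectivity metrics

All five metrics follow the standard definitions: AEC is the Pearson
correlation of Hilbert amplitude envelopes (signed — the absolute value is
*not* taken); PLV is the modulus of the mean phase-difference phasor; PLI the
modulus of the mean sign of the sine of the phase difference; COH and iCO the
band averages of the coherency modulus and of its imaginary part's modulus.
The band-pass (fourth-order Butterworth, applied forwards and backwards) and
the analytic transform are applied once to the full series, then windowed —
per-window filtering would re-introduce edge transients into every window.

Coherence inside a window uses Welch averaging over Hann-tapered,
50%-overlapping segments of width `min(window/4, 1 s)`. Two numerical
guards make this well defined down to the shortest windows: segments are
floored at 8 samples and capped at two-thirds of the window (so at least two
segments always fit), and segment spectra are evaluated on a frequency grid
of at least 256 points (equivalently, zero-padded), so the analysis band
always contains bins. Short-window coherence is therefore strongly biased
upwards — visible in the results as a bias floor — but identically so across
conditions, which is what matters for contrasts. The same segment-averaged
estimate would be identically 1 on a single unaveraged segment, which is why
the minimum of two segments is enforced rather than worked around.

## Leakage model and correction

Signal leakage is modelled as zero-lag inverse-distance mixing:
`x~_i = x_i + sum_j x_j / d_ij` with distances in mm, applied as a single
matrix product. Correction uses the symmetric multivariate approach — the
closest set of mutually orthogonal channels in the Frobenius sense, found by
alternating a polar-decomposition (orthogonal Procrustes) step with a
per-channel rescaling until the objective changes by less than 1e-10
relatively (500 iterations cap). The correction is applied to the
band-passed full-length series, once, before windowing; correcting inside
each window would make the leakage removal itself depend on the window
length, confounding the window-length analysis. Per the study's pipeline,
only AEC, COH and PLV are corrected; PLI and iCO are computed on the mixed,
uncorrected signals because their constructions already discard zero-lag
structure.

A known limitation, visible in the package's own network experiments: static
orthogonalization removes the *average* zero-lag correlation over the whole
run. When within-network coupling is itself dynamic, this overcorrects the
windows in which the network is active; amplitude metrics, which rely on
what correlation survives, suffer most, and in the default network regime
the corrected AEC contrast is essentially abolished while corrected PLV and
COH remain clearly detectable.

## Evaluation harness

Per metric and window length the harness computes four distribution
statistics (SD with n-1 denominator; skewness and kurtosis as standardized
third and fourth moments, so a Gaussian scores 0 and 3; and the excursion
statistic), Mann-Whitney tests of dynamic vs static runs, and
ground-truth agreement. The excursion statistic is the sum over maximal runs
strictly above or below the series median of run length times the run's
maximum absolute deviation; the length and height exponents are exposed
because the statistic is really a family, and the product form has a
degenerate corner (on an exactly two-level series it reduces to n times the
level gap regardless of run structure — real connectivity series are never
two-level, but it is why the unit test compares a noisy state series against
its own permutation rather than against white noise).

Because the truth is sampled at the signal rate while windows yield one value
each, estimates are interpolated to the sample grid with a natural cubic
spline through the (window centre, value) knots, clamped to the end values
outside the first and last centre. The truth's coupling levels are affinely
mapped to [0, 1] before scoring: Pearson correlation is unaffected and the
mean absolute error becomes unit-free. SNR is an amplitude ratio — per
channel, white noise with SD equal to the channel SD divided by the SNR is
added (a power-ratio interpretation is available via a flag). Window-length
effects are tested with the tie-corrected Friedman statistic over the
iterations-by-window-lengths table; all tests are two-sided at alpha = 0.01
with no multiplicity correction, matching the per-window-cross convention of
the figures this package reproduces.

For network runs, the active network of a window is the majority state among
the samples it covers (interpolating a categorical truth is ill-defined),
and the contrast compares the mean estimated connectivity over the active
mask's edges with the mean over all remaining edges, pooling windows across
realizations into one rank test per metric and window length, flagged only
when significant *and* in the within > outside direction.

## Tensor factorization

`ntf_decompose()` fits the constrained three-way model: L spatial
basis-vector pairs with orthonormal columns and non-negative temporal
loadings, minimizing the Frobenius reconstruction error (the norm the
objective leaves unstated; Frobenius is assumed). The alternating scheme
solves each subproblem exactly — polar (Procrustes) updates for the spatial
bases, and for the loadings a clipped projection, which *is* the exact
non-negative least-squares solution because the Khatri-Rao design has
orthonormal columns when both spatial bases do. A sign-rectification step
flips any component whose spatial map converged negative (the model is
sign-ambiguous in the spatial pair, but the non-negative loadings are not,
and an unrectified negative map is a permanently dead component). Each
update can only lower the objective, so the fit trace is non-increasing;
five random restarts guard against local minima, and components are ordered
by temporal energy since the model is permutation-ambiguous. L defaults to
4, one component per resting-state network. Negative tensor entries (signed
AEC) are clipped to zero with a logged count. Component edge maps are the
symmetrized outer product thresholded at the top 3% of off-diagonal edges
(ties included), and template matching maximizes total Jaccard similarity
over one-to-one assignments.

## Problem sizes

The package's experiment defaults and its test suite run at deliberately
reduced sizes chosen to keep a full evaluation on one CPU within minutes
while preserving every qualitative contrast: 300 s two-node runs with 10-20
iterations and a 12-point log-spaced window grid (0.25-30 s) — the
paper-scale grid of 80 window lengths is one config field away — and network
runs of 60 s over the 32 nodes belonging to at least one mask rather than
300 s over all 78 regions. The vignette-level claims above (monotone
coherence, alpha-band operation, Hopf bracketing, metric oracle equivalence,
contrast patterns) are each asserted by the test suite rather than taken on
trust.

## Worked example

```{r example}
library(dfcsim)

set.seed(1)
regime <- state_regime("slow")
lifetimes <- sample_lifetimes(regime, 300)
seq <- build_state_sequence(lifetimes, n_states = 3, fs = 250)
truth <- coupling_timecourse(seq, c(0.3, 0.6, 0.9))

x <- simulate_switching_mar(mar_state_specs(), seq)
xf <- bandpass(x, c(15, 25), 250)
series <- sliding_connectivity(xf, "COH", window_spec(2, 250),
                               c(15, 25), fs = 250, prefiltered = TRUE)
est <- interpolate_estimates(series, nrow(x), 250)
score_against_truth(est, truth)
distribution_summaries(series)
```

## Known limitations

Beyond the leakage-correction interaction noted above: the simulations are
models, not MEG — there is no forward/inverse projection, co-registration
error or spatially correlated sensor noise (SNR sweeps stand in for all
three); the MAR construction phase-locks the nodes by design, which favours
phase metrics; the two models live in different bands (beta for MAR, alpha
for the neural masses), so cross-model comparisons conflate model and band;
and surrogate-data testing of non-stationarity is out of scope.
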