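---
title: "Inferring promoter switching kinetics from MS2 transcription traces"
author: "burstKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring promoter switching kinetics from MS2 transcription traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstKinetics)
```

## The inference problem

Live imaging of nascent transcription with the MS2/MCP system yields, for
each nucleus, a fluorescence time series whose intensity is proportional
to the number of RNA polymerase II molecules currently elongating through
the reporter. The quantity of biological interest is hidden one level
below the signal: the sequence of individual initiation events, and below
that, the promoter's switching between transcriptionally permissive and
inactive states.

`burstKinetics` implements the full chain from trace to kinetic model:

1. **Deconvolution** of a calibrated trace into single Pol II initiation
   times on a 30 bp grid (genetic algorithm plus local optimization).
2. **Waiting-time extraction**: lag times between successive initiation
   events, pooled per genotype, summarized by a Kaplan–Meier survival
   estimate with Greenwood 95% bands.
3. **Multiexponential regression** of the survival function with a mixed
   linear/log objective, increasing the number of exponentials N from 2
   until the parametric curve stays inside the confidence band
   (parsimony: N equals the number of promoter states).
4. **Closed-form inversion** of the fitted distribution parameters into
   the switching and initiation rates of a two-state telegraph model or a
   three-state model with non-obligatory pausing, with error intervals
   propagated from suboptimal fits.

A synthetic-data stage (Gillespie simulation, kernel convolution, noise,
detection floor, postmitotic onset delays) generates ground-truth cohorts
for validating every step.

## The promoter models and their waiting-time distributions

The two-state telegraph model switches OFF → ON at rate $k_1^+$ and
ON → OFF at $k_1^-$, initiating at rate $k_{\mathrm{INI}}$ only while ON.
The three-state model adds a second inactive state (PAUSE) reachable only
from ON: ON → PAUSE at $k_2^-$, PAUSE → ON at $k_2^+$. Because a pause of
this kind detains only the subset of polymerases that happen to trigger
it, the model is *non-obligatory*.

Since initiation occurs only in ON, each initiation event leaves the
promoter in ON, and the waiting time to the next event is the first-passage
time of a Markov-modulated Poisson process started in ON. With generator
$Q$ and diagonal initiation matrix $R$,

$$S(t) \;=\; \langle \mathrm{ON}|\, e^{(Q-R)t} \,|\mathbf{1}\rangle
       \;=\; \sum_{i=1}^{N} A_i e^{\lambda_i t},$$

where the $\lambda_i < 0$ are the eigenvalues of $Q-R$ and the amplitudes
$A_i$ (summing to one) follow from its spectral decomposition
(`forwardDistribution()`). N promoter states give N exponentials — the
basis for reading the state count off the fitted survival function.

The inverse map is closed-form (`invertTwoState()`,
`invertThreeState()`). With the amplitude-weighted power sums
$S_k = \sum_i A_i \lambda_i^k$, the telegraph rates are

$$k_{\mathrm{INI}} = -S_1,\qquad
  k_1^- = S_1 - S_2/S_1,\qquad
  k_1^+ = \frac{S_3 S_1 - S_2^2}{S_1\,(S_1^2 - S_2)}.$$

The three-state solution additionally uses the symmetric functions of the
exponents $L_1=\sum_i\lambda_i$, $L_2=\sum_{i<j}\lambda_i\lambda_j$,
$L_3=\lambda_1\lambda_2\lambda_3$, and a square root of the discriminant
$(S_1L_1-S_2)^2-4L_3S_1$. Two remarks the implementation depends on:

* the $L_2, L_3$ terms must be the *elementary symmetric* polynomials,
  not power sums — with power sums the discriminant goes negative for
  every valid model, with the symmetric functions the round trip
  forward → invert is exact to $10^{-9}$ over thousands of random models
  (this is the package's central correctness oracle, see
  `test-model-inversion.R`);
* the two inactive states enter the distribution symmetrically, so the
  labeling is canonicalized with $k_2^+ \le k_1^+$: PAUSE is the
  longer-lived inactive state.

Derived quantities (`derivedKinetics()`): $T_{\mathrm{OFF}}=1/k_1^+$,
$T_{\mathrm{ON}}=1/k_1^-$ (or $1/(k_1^-+k_2^-)$ with pausing),
$T_{\mathrm{PAUSE}}=1/k_2^+$, steady-state occupancies, and burst size
$k_{\mathrm{INI}}/k_{\mathrm{OFF}}$ for the telegraph model. For the
three-state model the analogous ON-exit composite
$k_{\mathrm{INI}}/(k_1^-+k_2^-)$ is reported and labeled as such — the
two-state definition does not carry over unchanged.

```{r}
sna <- promoterModel(k1Plus = 1/24, k1Minus = 1/242, kIni = 1/9)
derivedKinetics(sna)
```

## The single-polymerase kernel and trace synthesis

A polymerase initiated at time 0 contributes no fluorescence until it has
transcribed the 41 bp pre-MS2 fragment, then a linear ramp while the
1292 bp stem-loop cassette is transcribed (fluorescence proportional to
the fraction of loops made, assuming uniform loop spacing), then one full
polymerase unit while the 4526 bp reporter body is transcribed, then
nothing (transcript retention at the site is set to 0 s by default but
kept as a parameter). At 45 bp/s the ramp spans 0.9–29.6 s and the signal
ends at 130.2 s. A trace is the sum of kernels over all initiation events,
sampled every 3.86 s (the movie frame interval).

`generateCohort()` adds what real movies have on top: a postmitotic onset
delay per nucleus (below), additive Gaussian noise, and a detection floor
that zeroes frames with three or fewer polymerases. The noise model is an
assumption — the magnitude of intensity noise in real traces is not part
of the model — and the default SD (0.2 polymerase units) is deliberately
mild; trace-level noise robustness is regression-tested at SD 0.25.
What the generator does *not* emulate: photobleaching, focus drift,
segmentation/tracking errors, and sister-chromatid structure (a real
transcription site sums two sister chromatids; traces here are a single
transcription unit). Passing recovery tests on synthetic cohorts
therefore validates the inference chain, not the microscopy.

## Deconvolution

Candidate initiation times live on a 30 bp grid (2/3 s at 45 bp/s), small
enough that at most one polymerase fits per position; a 35-min movie has
3150 positions. The placement minimizing the sum of squared residuals
between the observed and reconstructed trace is sought by a genetic
algorithm over index sets (population 100, up to 300 generations,
one-point crossover on the time axis, add/delete/shift mutations,
elitism) combined with greedy local optimization in which each event in
turn is repositioned at its best grid position, deleted if that lowers
the residual, or complemented by the best new event.

Two implementation choices matter in practice:

* **Initialization.** The integer placement problem has a benign
  continuous relaxation: non-negative least squares on fractional
  occupancies. The relaxation is solved by coordinate descent and
  rounded into integer seeds at several candidate event counts (the
  k-th event where the cumulative occupancy crosses $k-\tfrac12$), which
  places the search close to the optimum before the GA starts.
* **Observability floor.** Grid positions so close to the movie end that
  essentially none of their kernel is observed (signal energy below one
  squared polymerase-frame) are excluded as candidates; otherwise the
  optimizer could add "ghost" events there at no residual cost. The
  flip side is honest: events initiated in the last seconds of a movie
  are unidentifiable from the signal.

On noiseless, grid-aligned synthetic traces with inter-event spacing of
at least two grid steps and a mean spacing of about a minute, event
counts are recovered exactly and times to within one grid step (the
acceptance suite runs 50 such traces). For off-grid event times the count
remains exact at this density but an occasional event lands two steps
off — the discretized residual can genuinely prefer a neighboring
position. At high event density (one initiation every ~9 s, the strong-
promoter regime) per-event identifiability degrades — many placements
reconstruct the frame-sampled signal almost equally well — and the
deconvolution should be read as an event-density estimate: total counts
stay within a few percent, and moderate noise (SD 0.25) changes them by
about 1%.

## Waiting times and the survival estimate

Each trace is windowed to its stable part — frames with at least 1/5 of
the trace maximum — and waiting times are differences between successive
initiation events inside the window. The interval from the window start
to the first event is discarded (not a renewal interval from an observed
event). The final open interval is kept as right-censored by default;
dropping long open intervals would bias the tail of the distribution
downward, exactly where three-state behavior shows. Set
`censorFinal = FALSE` to reproduce the simpler convention.

`kmSurvival()` wraps the product-limit estimator with Greenwood variance
(`survival::survfit`, plain 95% band clipped to [0,1]; a log-log
transform is available). Without censoring it reduces exactly to the
empirical survival function.

## The fitting objective and its evaluation grid

The regression minimizes, over the $2N-1$ free parameters,

$$O = \frac{\alpha}{n}\sum_i (S(t_i)-S_e(t_i))^2
    + \frac{1-\alpha}{n}\sum_i (\log S(t_i)-\log S_e(t_i))^2,
  \qquad \alpha = 0.6,$$

balancing the short-time region (linear term) against the long-time tail
(log term). Optimization uses a softmax parametrization of the
amplitudes and log-transformed decay rates, a coarse screen of several
hundred candidate exponent sets (half log-uniform over the representable
range, half anchored at reciprocal survival-crossing times, where the
data actually decay) scored with least-squares amplitudes, BFGS
polishing (analytic gradient) of the best mutually distinct candidates,
and retention of all local optima for error intervals.

Two numerical choices stabilize the estimator and are worth stating
explicitly because they are easy to get wrong:

* The objective is evaluated at the **midpoints** of the constancy
  intervals of the product-limit step function. Evaluating a
  right-continuous step estimator exactly at its jump points understates
  the survival there by about one count; through the log term this
  compounds along the tail and systematically shortens the inferred slow
  timescale (about 5% on $T_{\mathrm{ON}}$ in the strong-promoter
  regime).
* Grid points where fewer than 30 subjects remain **at risk** are
  excluded from the objective and from the acceptance check. The deepest
  tail of the estimator is supported by a handful of order statistics
  whose log has O(1) noise; left in, it dominates the log term, and the
  normal-approximation band it carries is meaninglessly narrow. The
  floor is an absolute count, so its effect vanishes in relative terms
  as data grow.

Large grids are thinned evenly to at most 3000 points for speed; at that
density the fit is indistinguishable from the full grid.

## Model selection, the obligatory-pause test, and error intervals

`selectNumStates()` fits N = 2, then 3, up to 4, and returns the first
fit whose parametric curve stays inside the Greenwood band at every grid
time at or above the 10 s cutoff (the same short-time exclusion as the
goodness-of-fit KS test: residual deconvolution placement errors
concentrate below ~10 s and would otherwise fail every model). The
obligatory-pause alternative — every polymerase pauses — constrains the
distribution parameters to $\sum_i A_i\lambda_i = 0$, i.e. zero density
at lag zero; `fitConstrainedObligatory()` fits on that manifold (four
free parameters) and, on data from non-obligatory simulations, is
rejected because the constrained curve cannot follow the finite density
of short waiting times.

`modifiedKsTest()` is a one-sided one-sample KS test of the observed
waiting times above the cutoff against the fitted distribution truncated
and renormalized at the cutoff. The one-sided direction (empirical CDF
above the fitted) was chosen as the direction sensitive to the typical
failure mode, surplus short waiting times; this is a convention choice.
Whether acceptance should use every grid time or a subsample is likewise
open; every retained grid time is used.

Error intervals (`errorIntervals()`, overflow ratio 2) are the
per-parameter minima and maxima over all local optima whose objective is
at most twice the best — a cheap, honest summary of the optimization
landscape rather than a sampling-theory confidence interval.
`kineticsReport()` pushes every retained solution through the inversion
and reports the same envelope on rates and derived quantities.

## Postmitotic gaps

The delay between mitosis and first activation is modeled as a mixture
of Erlang distributions with one, two or three rate-limiting steps of
common mean duration $b$:

$$S(t) = p_1 e^{-t/b} + p_2\bigl(1-P(2,t/b)\bigr)
       + (1-p_1-p_2)\bigl(1-P(3,t/b)\bigr),$$

with $P$ the regularized incomplete gamma function (the $\gamma(3,x)/2$
normalization in the unregularized form is what makes the two readings
identical — stated to forestall a factor-of-two bug). This is exactly the
equal-timescale (confluent/Jordan) limit of the three-exponential family:
as the $\lambda_i$ coalesce at $-1/b$ the family degenerates to the span
of $e^{-t/b},\ t e^{-t/b},\ t^2 e^{-t/b}$, and matching mixture weights
gives $S(t) = e^{-u}(1 + (p_2{+}p_3)u + p_3 u^2/2)$, $u=t/b$.
`equalLambdaLimitCheck()` verifies the identity numerically through two
independent routes. `fitGap()` reuses the mixed objective on the
Kaplan–Meier estimate of onset delays; the mixture weights are the
weakly identified direction (a single cohort of $10^4$ delays determines
$b$ to a few percent but $p_2$ only to ~±0.1), so recovery is asserted
on the bias across seeds and on the fitted curve, not on single-run
weights.

Cohort defaults ($p_1=0.4$, $p_2=0.3$, $b=60$ s) describe a population
in which most nuclei activate within a few minutes of mitosis with a
dispersed minority — a generic early-embryo regime; they are assumptions
of the generator, not measurements.

## Problem sizes used by the test and acceptance suites

All simulation sizes are stated here as the package's validation
choices: waiting-time recovery uses $3\times10^5$ oracle-sampled waiting
times (the slow-timescale estimator's spread at $10^5$ is ~±5%, right at
the tolerance it is tested against); state-count selection uses 20
replicates of $10^4$ waiting times per model class; deconvolution
recovery uses 50 noiseless traces of ~6 events each plus dense-trace
count regressions; Greenwood calibration uses 100 replicates of $10^4$
exponential draws probed at deciles; gap recovery uses 20 cohorts of
$10^4$ delays. The end-to-end pipeline test runs a small cohort (6
nuclei, 700 s) and checks the report bundle and its reproducibility
under fixed seeds rather than parameter accuracy, which the dedicated
stages already cover; at realistic event densities the deconvolution's
placement jitter inflates the short-waiting-time region, which is
precisely why the short-time cutoff exists.

## Known limitations

* Models beyond three states, initiation from more than one state, and
  time-varying rates are out of scope; the inversion formulas exist only
  for the two printed model families.
* The obligatory-pause model is handled only through its constrained
  distribution fit; no generator for it is simulated, since its state
  topology is not determined by the constraint alone.
* Per-event deconvolution accuracy degrades gracefully but measurably
  with event density; kinetic estimates from dense traces lean on the
  distributional pipeline, not on exact placements.
* The uniqueness domain of the inverse problem is reported empirically
  per input (validity flags) rather than characterized analytically.
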