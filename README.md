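# burstKinetics

Transcription in single cells happens in bursts: promoters switch
stochastically between permissive and inactive states, and RNA
polymerase II initiates only while the promoter is permissive. Live
MS2/MCP imaging makes this visible as a fluorescent focus per nucleus
whose intensity is proportional to the number of polymerases currently
elongating through the reporter — but the kinetics of interest (how long
the promoter stays ON, how often it fires, whether there is a second,
pause-like inactive state) are hidden behind the optical signal.

`burstKinetics` implements a complete trace-to-kinetics inference
pipeline for this problem:

* **Promoter models** — two-state telegraph (OFF ⇄ ON, initiation at
  rate k_INI while ON) and three-state non-obligatory pause models
  (a second inactive state entered from ON), with exact Gillespie
  simulation and the exact forward map from rates to the waiting-time
  survival function `S(t) = Σ A_i exp(λ_i t)` (the interval distribution
  of the Markov-modulated Poisson process started in ON).
* **Signal synthesis** — single-polymerase trapezoid kernel
  (41 bp pre-MS2 / 1292 bp 24xMS2 / 4526 bp reporter at 45 bp/s),
  3.86 s frame sampling, Gaussian noise, a >3-polymerase detection
  floor, and mixed-gamma postmitotic onset delays.
* **Deconvolution** — recovery of single Pol II initiation times on a
  30 bp grid by a genetic algorithm with non-negative-least-squares
  seeding and greedy local optimization.
* **Waiting-time analysis** — 1/5-max trace windowing, right-censored
  waiting-time extraction, genotype pooling, Kaplan–Meier survival with
  Greenwood 95% bands.
* **Multiexponential regression** — mixed linear/log objective
  (α = 0.6), multi-start gradient optimization, parsimony-based
  selection of the number of promoter states, a constrained fit for the
  obligatory-pause alternative (Σ A_i λ_i = 0), a cutoff
  Kolmogorov–Smirnov goodness-of-fit test, and error intervals from
  suboptimal optima (overflow ratio 2).
* **Model inversion** — closed-form recovery of all kinetic rates from
  the fitted distribution parameters for both model families, e.g.
  k_INI = −S₁, k₁⁻ = S₁ − S₂/S₁, k₁⁺ = (S₃S₁ − S₂²)/(S₁(S₁² − S₂)) for
  the telegraph model, with derived state durations, occupancies and
  burst size k_INI/k_OFF.

See the methods vignette (`vignettes/promoter-kinetics.Rmd`) for the
model, the numerical choices and the validation strategy.

## Worked example

Simulate waiting times from a strong TATA-promoter regime (mean OFF
24 s, mean ON 242 s, one initiation per 9 s), estimate the survival
function, select the number of states, and invert back to rates:

```r
library(burstKinetics)

sna <- promoterModel(k1Plus = 1/24, k1Minus = 1/242, kIni = 1/9)
derivedKinetics(sna)
#> derived kinetics
#>   T_ON = 242 s, T_OFF = 24 s, T_PAUSE = NA s
#>   p_ON = 0.91, p_OFF = 0.0902, p_PAUSE = NA
#>   burst size = 26.89 transcripts per ON period

x <- sampleWaitingTimes(forwardDistribution(sna), 3e5, seed = 1)
s <- kmSurvival(waitingTimeSet(x, genotype = "sna_like"))
fit <- selectNumStates(s, fitConfig(seed = 1))
fit
#> 2-exponential fit: objective 2.091e-06, accepted
#> 2-exponential survival parameters
#>   A1 = 0.07971, lambda1 = -0.0390734 /s (timescale 25.6 s)
#>   A2 = 0.9203, lambda2 = -0.117033 /s (timescale 8.54 s)

invertTwoState(fit@best)
#> 2-state kinetic rates
#>   k1_plus   0.0412644 /s
#>   k1_minus  0.00402306 /s
#>   k_ini     0.110819 /s
```

The two exponential timescales (25.6 s and 8.5 s) are *not* the state
durations; the closed-form inversion disentangles them into
T_OFF = 1/k₁⁺ ≈ 24.2 s, T_ON = 1/k₁⁻ ≈ 248.6 s and one initiation every
1/k_ini ≈ 9.02 s — recovering the generating regime from the
waiting-time distribution alone.

The full pipeline (simulate → deconvolve → survival → fit → invert →
report) runs from one call:

```r
cfg <- pipelineConfig(model = presetModel("two_state_fast"),
                      cohort = cohortConfig(nNuclei = 50, seed = 1),
                      outDir = "run1")
res <- runPipeline(cfg)   # writes events.csv, survival.csv, fit.json,
                          # kinetics.json, heatmap.csv, log.txt
```

A thin command-line wrapper over these functions is provided at
`inst/scripts/run_pipeline.R`.

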