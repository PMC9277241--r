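# turbidive

Movement-ecology tools for asking whether a pursuit-diving seabird's
foraging is constrained by **underwater visibility** — the joint effect of
solar elevation, cloud cover and water turbidity (Secchi-disc depth, Zsd).
The package is written for biologgers and movement ecologists: it takes GPS
fix tables, time-depth-recorder (TDR) traces and gridded environmental
fields, and carries them through trip segmentation, dive/bout detection,
covariate annotation, a covariate-dependent hidden Markov movement model,
and penalized-spline models of dive rate and dive depth. A seeded synthetic
colony generator with full ground truth makes every stage testable as a
parameter-recovery problem.

## The models

**Movement.** Step lengths `l_t` (gamma) and turning angles `φ_t` (von
Mises) are emitted from a 3-state chain — rest, area-restricted search
(ARS), transit, labelled by ascending step mean — whose transition matrix
is a multinomial logit in standardized Secchi depth:

    Γ_ij(z) ∝ exp(β0_ij + βz_ij · z)   (i ≠ j, diagonal as reference)

fitted by direct numerical maximization of the forward log-likelihood
(compiled recursion, working-scale BFGS, multi-start). The Zsd-informed and
intercept-only models are compared by AIC, by decoded-state agreement, and
by hit/miss/precision of "decoded ARS" as a dive predictor. Stationary and
switching probabilities are reported as curves over Zsd with delta-method
or bootstrap intervals.

**Dive rate.** Counts per 5-min fix, negative binomial with log link:

    log μ = te(α, z) + s(cloud) + s_cc(τ) + b_bird,   AR(1) within trips

with shrinkage (`ts`) bases throughout, REML smoothing selection at
`gamma = 1.2`, a cyclic cubic spline for time of day τ, and a two-step
AR(1) whitening of the working model. Goodness of fit: deviance explained
and the AUC of `P(N>0) = 1 − (θ/(θ+μ))^θ` against observed dive presence.

**Dive depth.** Gaussian model of the bout maximum depth adding `s(water
depth)` (expected to be selected against) and the decoded behavioural state
(contrasts vs rest). A bout is a run of dives separated by gaps below the
bout-ending criterion, estimated from the fast/slow inter-dive interval
mixture by weighted broken-stick nonlinear least squares.

## Worked example

```r
library(turbidive)
run <- run_all(sim_config(seed = 99), n_restarts = 1)
print(run)
```

```
<run_report> seed=99 hash=0849a77f
  trips: 9 (mean 41.0 h, max range 119.5 km)
  dives: 769 (48.1 +/- 31.2 per bird-day; depth 9.9 +/- 4.2 m, max 22.3 m)
  Zsd encountered: 7.0 +/- 2.0 m
  HMM: dAIC(null - zsd)=51.1, agreement 99.7%, 61.7% of dive fixes in ARS
  dive rate: 25.2% deviance explained, AUC 0.78
  dive depth: 28.3% deviance explained
  dives below civil twilight: 0.00%
```

Reading the report: 8 simulated birds yielded 9 foraging trips (one track
dipped briefly inside the 5 km colony radius and split). The Secchi-informed
HMM is preferred by 51 AIC units while decoding 99.7% of points identically
to the null model — the covariate sharpens *transition* structure rather
than relabelling states — and most dive-containing fixes decode as ARS. The
dive-rate model recovers a quarter of the deviance and discriminates
dive-present fixes at AUC 0.78; no simulated dive occurs below civil
twilight because the generator gates dives on the fix's solar angle, so the
pipeline must report exactly 0%.

The `analysis/` directory runs the same chain stage by stage
(`01_simulate.R` … `07_report.R`, plain CSV interfaces, artifacts under
`results/`), which is the easiest place to see each module's inputs and
outputs.

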