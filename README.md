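# telemcjs

Survival, fishing and natural mortality of large lake fish from combined
high-reward tagging and fixed-station acoustic telemetry.

Recreational fisheries managers need to know how much of a population's
total mortality (*Z*) is taken by anglers (fishing mortality, *F*) and how
much is natural (*M*). `telemcjs` implements a workflow for separating the
two in large-lake fisheries: high-reward ($100) anchor tags push angler
reporting toward 100% and so inform *F*, while a fixed receiver array
detects acoustically tagged fish moving between lake sections and so
informs *M*. The package covers the whole path from raw hourly detection
records to posterior distributions of the mortality rates, catchability
and density.

## The model

Encounter histories are quarterly (winter Jan–Mar, spring Apr–Jun, summer
Jul–Sep, autumn Oct–Dec). For fish *i* in season *t*, the individual
state-space Cormack–Jolly–Seber model tracks a latent alive state
*z*(i,t), with *z* = 1 at release and

    z[i,t+1] ~ Bernoulli(z[i,t] * phi[i,t])        seasonal survival
    y[i,t]   ~ Bernoulli(z[i,t] * rho[i,t])        angler recapture (reported)
    m[i,t]   ~ Bernoulli(z[i,t] * T[i,t] * delta[i,t])   detected moving
    x[i,t]   ~ Bernoulli(z[i,t] * S[i,t] * kappa[i,t])   spawning state

where *T* flags an active transmitter and *S* the species' spawning
season. The four probabilities are logit-linear:

    logit(phi)   = b_phi0   + b_phix * x + b_phiY * Y
    logit(rho)   = b_rho0   + b_rhoY * Y
    logit(delta) = b_delta0 + b_deltaS * S + b_deltaY * Y
    logit(kappa) = b_kappa0 + b_kappaL * L + b_kappaY * Y

with *L* = (fork length − 600)/100 (length projected by a seasonal Von
Bertalanffy curve) and *Y* the standardized calendar year. The seven
non-intercept coefficients carry spike-and-slab priors with Bernoulli(1/2)
selection indicators (stochastic search variable selection): Normal(0, 3)
when selected, Normal(0, 0.03) when not. Posterior quantities convert to
management scales as annual survival `phi^4` (spawners:
`phi_ns^3 * phi_sp`), annual recapture `1 − (1 − rho)^4`,
`F = −log(1 − rho_annual)`, `M = −log(phi_annual)`, catchability
`q = rho/E` and density `D = (C/rho)/area`.

Fitting is by a purpose-built Metropolis-within-Gibbs sampler (Rcpp):
exact categorical Gibbs draws of each fish's death time, Bernoulli Gibbs
for unobserved spawning states, adaptive random-walk Metropolis plus
conditional-prior independence proposals for the coefficients, and
conjugate Gibbs for the indicators. Anchor-tag loss is estimated from
double- versus single-tagged recaptures with a zero-truncated binomial
model.

## Worked example

```r
library(telemcjs)

# simulate a six-year study (releases, transmitters, detections, recaptures)
design <- sim_design("RainbowTrout", years = 2008:2013,
                     n_per_year = c(35, 35, 35, 35, 30, 30),
                     tag_life_days = 4000)
enc <- simulate_encounters(design, seed = 42)

fit <- cjs_fit(enc, control = cjs_control(n_chains = 5, n_iter = 20000),
               seed = 1)
predict(fit, "survival", scale = "annual")
#>   parameter  estimate     lower     upper         sd error significance
#> 1  quantity 0.7794261 0.7126785 0.8402009 0.03251586   8.2        1e-04
predict(fit, "recapture", scale = "annual")
#>   parameter  estimate     lower     upper         sd error significance
#> 1  quantity 0.1531834 0.1079005 0.2052268 0.02472787    32        1e-04
```

The first table says a 650 mm non-spawner has an annual interval survival
probability of about 0.78 (95% CRI 0.71–0.84); the second that its annual
probability of being caught and reported by an angler is about 0.15
(0.11–0.21) — close to the generating values (0.77 and 0.14), since the
data were simulated from the model. `summary(fit)` gives the full
coefficient and
indicator table (posterior mean, 95% CRI, SD, percent relative error,
significance, R-hat), `derive_rates(fit, effort = 4.88, catch = 4845)`
the fisheries quantities, and

```r
fit_tagloss(18, 7, seed = 1)
#> Zero-truncated binomial tag-loss model
#>   recaptures: 18 with both tags, 7 with one tag
#>   per-tag loss p: 0.183 (95% CRI [0.081, 0.324])
#>   double loss p^2: 0.0374 (95% CRI [0.0065, 0.1051])
```

the anchor-tag loss posterior for 18 double- and 7 single-tagged
recaptures.

For raw data, `run_pipeline()` chains the reduction steps —
`filter_hourly()` (discard sparse and post-tag-life detections),
`assign_daily_sections()` (most-detections / fewest-receivers /
smallest-area tie-break), `classify_post_release()` (30-day rule),
`infer_spawning()` (hiatus and spawning-ground rules) and
`build_encounter_data()` — then fits and summarizes.

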