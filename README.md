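# stopmix

Estimating how long migratory birds stay at a stopover site, when they
arrive, and how many of them use the site over a season — from daily
resightings of individually marked birds plus scan samples of marked
and unmarked birds — while accounting for *individual heterogeneity* in
how likely birds are to stay and to be seen.

The package is aimed at movement and population ecologists working with
mark–resight data from staging sites (the motivating system is shorebird
staging during spring migration, where 1–2-day transients and
long-staying refuellers mix in one flock, and where some birds feed in
view of observers while others do not).

## The models

**Jolly–Seber superpopulation model.** Marked birds arrive over `K`
daily occasions with entry probabilities `β_t` (Σβ_t = 1), remain each
following day with daily staying probability `φ`, and while present are
resighted each day with encounter probability `p`. The superpopulation
is every marked bird that used the site during the window, including
those never seen; its size is recovered from the probability of being
detected at least once. The maximum-likelihood engine (`fit_ml()`)
implements the Schwarz–Arnason formulation: each observed history
contributes a sum over all latent (entry day, departure day) pairs
consistent with its first and last sightings, and
`N̂ = n / (1 − Pr(never detected))`. Model structures are written in
the field's shorthand (`"bt_phi._pt"` = time-dependent entry, constant
staying, daily encounter) and compared by AICc, selecting the model
with the fewest parameters within ΔAICc < 2.

**Finite-mixture heterogeneity.** Two latent classes of birds with
proportions `Ω` may differ in staying probability (`φ_h`), encounter
probability (an additive class offset on the logit scale, `p_{t+h}`),
or both. Ignoring such heterogeneity biases superpopulation size and
stopover duration substantially; `run_bias_study()` quantifies this
over ten tabulated two-class scenarios.

**Bayesian state–space formulation** (`run_mcmc()`), the core of the
package: parameter-expanded data augmentation with inclusion indicators
`w_i ~ Bernoulli(Ψ)`, class labels `h_i ~ Categorical(Ω)`, presence
states `z_{i,t}` (arrive once, stay geometrically, no re-entry), and
detections `y_{i,t} ~ Bernoulli(w_i z_{i,t} p_{t,h_i})`. Derived
per draw: marked superpopulation size `M* = Σ w_i`, individual stopover
durations `S_i = w_i Σ_t z_{i,t}`, and the population mean stopover
duration `S̄ = Σ S_i / M*` — averaged over **all** included birds,
including never-observed ones. A custom collapsed Gibbs sampler updates
each bird's (class, entry, departure) jointly by an exact categorical
draw, with conjugate parameter updates; it is validated against an
exhaustively enumerated exact posterior (`exact_mstar_posterior()`).

**Mark-ratio (ring-density) scaling.** Scans of `N_s` birds containing
`m_s` marked ones give a conjugate Beta posterior for the marked
proportion `π` (`estimate_pi()`; same-day scans without replacement are
pooled by `merge_scans()`), and total stopover population size is
`N* = M*/π`, computed draw-by-draw so the uncertainty in both factors
propagates (`total_population()`).

## Worked example

Simulate the hardest heterogeneity scenario — 20% of birds stay long
and are easily seen (φ = 0.9, p = 0.8), 80% stay briefly and are seldom
seen (φ = 0.5, p = 0.2), 500 marked birds over 15 days — then fit the
classical no-mixture model and the two-mixture Bayesian model:

```r
library(stopmix)

scn <- make_scenario(5, seed = 7)
sim <- simulate_histories(scn)
sim$histories
#> Encounter histories: 226 individuals x 15 occasions
#>   detections: 617 (2.73 per individual)

fit_ml(sim$histories, "bt_phi._p.", n_starts = 1)
#> Maximum-likelihood JS superpopulation fit: bt_phi._p.
#>   n observed = 226, loglik = -1157.874, K params = 17, AICc = 2352.69
#>   N_hat = 246.9 (SE 5.6), phi = 0.761, p(mean) = 0.760
```

Only 226 of the 500 marked birds were ever seen, and the no-mixture
model estimates a marked superpopulation of ~247 — half the truth —
because the many rarely-seen short-stayers are nearly invisible to it.
The two-mixture Bayesian model, combined with scan samples in which
roughly 1 bird in 200 is marked, recovers the truth within its credible
interval and scales up to the whole population:

```r
scans <- simulate_scans(sim$truth, n_unmarked_multiplier = 199, seed = 8)
draws <- run_mcmc(augment(sim$histories, factor = 5), "bt_phih_p.+h",
                  n_iter = 6000, n_burn = 2000, n_chains = 2, seed = 7,
                  scans = merge_scans(scans))
stopover_summary(draws)
#> Stopover summary
#>           quantity  estimate       lcl       ucl
#>             M_star 6.644e+02 4.140e+02 1.044e+03
#>  mean_sod_realized 2.857e+00 2.333e+00 3.550e+00
#>  mean_sod_from_phi 2.417e+00        NA        NA
#>      arrival_day50 7.000e+00 7.000e+00 9.000e+00
#>             pi_hat 5.457e-03 4.621e-03 6.357e-03
#>             N_star 1.226e+05 7.343e+04 1.972e+05
```

`M_star` is the marked superpopulation (truth: 500; the no-mixture
estimate 247 sits far below the interval), `mean_sod_realized` the mean
number of days included birds were present (truth here: 2.7 days),
`arrival_day50` the day by which half the population had arrived
(truth: day 8), and `N_star = M*/π` the total number of birds of which
the marked ones are a fraction `pi_hat`. With the default augmentation
factor 3 this run flags that the posterior of `M*` piles up near the
augmented size — the printed warning is the cue to raise `factor`, as
done above.

Field data are ingested from per-day 0/1 CSV files or classic `.inp`
records (`read_histories()`), restricted to an analysis window such as
10–30 May (`filter_window()`), with scan samples from CSV
(`read_scans()`); see the small synthetic season shipped under
`inst/extdata/`.

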