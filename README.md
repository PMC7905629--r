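# asmove — directional Arnason-Schwarz mark-recapture models for acoustic telemetry

`asmove` estimates weekly survival and seasonal movement probabilities of
tagged fish from stationary acoustic-telemetry detection logs, for study
systems where receivers at the passages between two water bodies (a sound
and the open gulf) are arranged in **paired inner/outer lines** so the
order of line crossings reveals a fish's direction of travel. It was
built for partial-migration questions of the kind posed for Pacific
herring: do fish leave the sound for the gulf after spawning, when do
they return, and which entrances do they use?

## The model

The core is a Bayesian Arnason-Schwarz (multistate Cormack-Jolly-Seber)
hidden Markov model on weekly detection occasions. States are
`{expired, spawn array, interior array, sound-at-large, three entrance
arrays, gulf}`; emission is deterministic (a fish within range of an
array is always detected; an undetected fish is expired, at large in the
sound, or in the gulf). Transition probabilities factor as
`phi^{rs} = S^r psi^{rs}` — survival times movement-given-survival — with
mortality possible only in the sound-at-large and gulf states, and all
parameters binned by season and (optionally) a median-split fish class.

Directional information enters through **empirical-Bayes Dirichlet
priors**: at each entrance `r`, assigned passages are tallied per class
`y` and season `k` into gulf-to-sound counts `d4` and sound-to-gulf
counts `d8`, a stay/leave ratio `q_r` converts them into a stay
pseudo-count `drr = q_r (d4 + d8)`, and the entrance movement simplex
gets the prior `Dirichlet(d4 + 1, drr + 1, d8 + 1)`. Remaining movement
blocks get `Dirichlet(2, ..., 2)` and free survival probabilities
`Beta(2, 2)`. The posterior is computed by Gibbs sampling with exact
forward-filtering backward-sampling (FFBS) of the latent paths (C++
core), with Gelman-Rubin diagnostics and marginal-deviance DIC.

Because telemetry data of this kind are rarely shareable, the package
includes a first-class synthetic-data generator (`simulate_dataset()`)
that emits the raw tables — detection log, receiver registry, tag
deployments — under the full generative model, including the fine-scale
inner/outer detection geometry and its corruption modes.

## Worked example

```r
library(asmove)

# simulate a small synthetic study (80 fish, two-year weekly grid)
sim <- simulate_dataset(simulation_scenario(n_fish = 80), seed = 42)

# discretize raw detections onto the weekly grid
presence <- assign_presence(sim$detections, sim$receivers, sim$grid)
obs <- build_observation_matrix(presence, sim$deployments, sim$grid)
print(obs)
#> Weekly observation matrix: 80 fish x 105 occasions
#>   active fish-occasions: 3542 ; detections: 533

# directional passages at the entrance arrays and the empirical prior
passages <- extract_passages(sim$detections, sim$receivers, sim$grid)
table(passages$direction)
#> gulf_to_sound sound_to_gulf    unassigned
#>            10            34           172
q <- sapply(c("hinchinbrook", "strait", "passages"),
            function(e) estimate_q(presence, e, obs = obs))
round(q, 2)
#> hinchinbrook       strait     passages
#>         0.43         1.18         1.29
counts <- stay_pseudocount(tabulate_counts(passages, sim$classing, sim$grid), q)
priors <- build_priors(counts)

# fit (short demonstration run; defaults are 4 x 200,000 sweeps)
fit <- asmove(obs, priors, classing = sim$classing,
              chains = 2, iterations = 2000, burnin = 500, thin = 5, seed = 1)
print(fit)
#> Directional Arnason-Schwarz model fit
#>   fish: 80  classes: 2  seasons: 4
#>   chains: 2  draws/chain: 300  ( 2000 sweeps, burn-in 500 , thin 5 )

head(subset(as.data.frame(summary(fit)), grepl("psi\\[5>", parameter)), 4)
#>       parameter    median      lower     upper      rhat
#> 81 psi[5>4|0,1] 0.2297105 0.07459519 0.4709761 0.9989510
#> 82 psi[5>4|0,2] 0.2811369 0.02590205 0.7822764 0.9992684
#> 83 psi[5>4|0,3] 0.1917818 0.06845747 0.3768518 1.0201693
#> 84 psi[5>4|0,4] 0.6163556 0.22940178 0.8933678 0.9983616

dic(fit)$pD
#> [1] 25.31432
```

The rows shown are the weekly Hinchinbrook-to-sound movement
probabilities `psi[5>4|class,season]`: for class-0 (lighter) fish the
posterior median rises from 0.23 in the first spring/summer to 0.62 in
the final fall/winter — fish at that entrance become much more likely to
re-enter the sound in late fall, the return leg of the seasonal
migration. `lower`/`upper` are the equal-tailed 90% interval and `rhat`
the Gelman-Rubin factor (values near 1 indicate converged chains). A
positive `pD` is the effective number of parameters behind the DIC.

`coef(fit)`, `plot(fit)` (trace plots), `simulate(fit)` (posterior
replicate datasets) and `covariate_effect(fit)` (logit-scale class
contrasts with 90% significance flags) complete the fit interface. The
same pipeline runs from CSV inputs via `cmd_fit()` with a YAML
configuration, and `inst/cli/asmove` wraps `cmd_simulate` / `cmd_fit` /
`cmd_diagnose` for shell use.

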