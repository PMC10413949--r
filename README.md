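# gutsorb

Toxicokinetics of hydrophobic organic chemicals (HOCs) exchanging
between microplastic and the other constituents of simulated gut fluid
— water, bile-salt/fatty-acid micelles, digestible lipid and a
polyoxymethylene (POM) passive sampler — while the lipid is being
digested.

The package is for environmental toxicologists and exposure modellers
who work with in vitro gut-fluid (bioaccessibility) assays and want a
tested, reproducible implementation of the full computational chain:
partition-coefficient estimation, lipolysis kinetics, a digestion-aware
exchange model with sampling events, rate-constant inference, and
bioavailability scenario metrics — plus a seeded synthetic-data
generator so every stage can be exercised end to end without lab data.

## The model

Chemical mass is conserved across phases; on the system-volume basis
(µg/L),

C_total = C_w + C_micelle + C_oil + C_POM + C_LDPE,

with each sorbed phase at equilibrium C*_x = K_x · C_w (solid basis,
µg/kg; K_x in L/kg). Three pieces sit on top of this balance:

1. **Partition estimation.** A POM sampler anchors the freely dissolved
   concentration (C_w = C*_POM / K_POM); the closed-system balance then
   has a unique rearrangement for K_micelle or K_oil
   (`estimate_k_micelle()`, `estimate_k_oil()`), and coefficients across
   a congener series are summarised as log-linear free-energy relations
   log10 K = a·log K_OW + b (`fit_loglinear()`).
2. **Digestion.** Free fatty acids are liberated by first-order
   saturating kinetics FFA(t) = FFA_max(1 − e^(−k_FFA t))
   (`ffa_at()`, `fit_ffa()`); each FFA joins the micelle pool and each
   three FFA consume one triglyceride, so [micelle]_t grows and [oil]_t
   shrinks (`compartments_at()`).
3. **Exchange.** Micelles/oil/water/POM form one instantaneously
   equilibrating pool with freely dissolved fraction
   f_w(t) = 1/(1 + ΣK_x[x]_t); the rate-determining biphasic LDPE
   exchange obeys dC_LDPE,fast/dt = k1·C_w − k2·C_LDPE,fast with a
   frozen slow reservoir over 72 h. `simulate_exchange()` integrates
   this with discrete strip-removal events; `fit_k1k2()` recovers k1,
   k2 from observed C*_LDPE series; `derive_kp()` gives
   K_P = k1/(k2·[LDPE]·f1); `fold_increase()` and
   `bioavailability_reduction()` compute the scenario metrics.

## Worked example

```r
library(gutsorb)

# 1. noiseless synthetic partition experiments, inverted and refitted
sp  <- scenario_spec(noise_cv = 0)
ds  <- make_partition_dataset(sp)
mic <- estimate_k_micelle(ds[ds$experiment == "micelle", ])
fit_loglinear(mic$log_kow, log10(mic$k_micelle))
#> log-linear relation: y = 0.99 * log Kow + 0.61
#>   r2 = 1.000  n = 160

# 2. digestion kinetics at the experimental timepoints
tt <- c(0, 2, 4, 6, 8, 10, 24, 48, 72)
fit_ffa(tt, ffa_at(tt, enzyme_digestion_params("high")))
#> FFA kinetics fit (converged, n = 9):
#>   FFA_max = 10.53 (SE 8.4e-16) uM
#>   k_FFA   = 0.079 (SE 1.7e-17) 1/h

# 3. an under-loaded plastic (10% of its kinetic equilibrium) through
#    72 h of digestion, no strip removals
sys <- gut_system(removal_times = numeric(0))
kp  <- kinetic_params(k1 = 9298, k2 = 1,
                      k_micelle = 10^(0.99 * 6.71 + 0.61),
                      k_oil     = 10^(0.85 * 6.71 + 2.21),
                      k_pom     = 10^predict(default_k_pom_relation(), 6.71))
kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
s0 <- initialize_state(sys, kp, c_total = 80)
s0$m_pool      <- s0$m_pool + 0.9 * (s0$m_ldpe_fast + s0$m_ldpe_slow)
s0$m_ldpe_fast <- 0.1 * s0$m_ldpe_fast
s0$m_ldpe_slow <- 0.1 * s0$m_ldpe_slow
traj <- simulate_exchange(sys, kp, s0, tt)
round(traj$c_ldpe_star, 1)
#> [1]  2.3 11.4 12.6 12.8 12.8 12.8 12.8 12.8 12.8
fold_increase(traj)
#> [1] 5.51
bioavailability_reduction(traj)
#> [1] 0.115
```

The plastic concentration (µg/kg) relaxes from its depleted start
toward the k1/k2 equilibrium within ~6 h (the relaxation rate is
k2 + k1·f_w ≈ 1 h⁻¹). The solid-basis fold increase here is 5.5
rather than the fast-reservoir ratio of 10 because half of the
plastic-bound chemical sits in the frozen slow reservoir (f1 = 0.5).
The bioavailability reduction — the share of total gut chemical newly
sequestered by plastic — is small (0.12%) because this single-congener
system holds most of its chemical in the oil phase; reductions grow
with hydrophobicity and with the plastic-to-pool affinity ratio. See
`vignette("gut-microplastic-toxicokinetics")` for the model's
assumptions and design choices.

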