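---
title: "Modelling chemical exchange on microplastics during gut digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemical exchange on microplastics during gut digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsorb)
```

## The problem

When an organism ingests both contaminated food and contaminated
microplastic, digestion changes the sorptive composition of the gut
content: lipase hydrolyses triglycerides, liberating free fatty acids
(FFA) that join the mixed micelle pool while the oil pool shrinks.
Hydrophobic organic chemicals (HOCs, with polychlorinated biphenyls as
the canonical test family) released from the digested lipid repartition
across water, micelles and plastic. Because ingested microplastic is
essentially not absorbed across the gut lining, whatever chemical it
picks up is egested — so plastic can act as a sink that *reduces*
chemical bioavailability during digestion. `gutsorb` implements the
complete computational chain needed to quantify this in an in vitro
gut-fluid system: partition-coefficient estimation from passive-sampler
readings, digestion kinetics, a digestion-aware exchange model with
sampling (strip-removal) events, rate-constant inference, and scenario
metrics.

## Model structure

### Closed-system mass balance

All chemical mass in the system is conserved across phases
(water, micelles, oil, a polyoxymethylene (POM) passive sampler and
low-density polyethylene (LDPE) strips). On the system-volume basis
(µg per litre of system volume),

$$C_\mathrm{total} = C_w + C_\mathrm{micelle} + C_\mathrm{oil} +
  C_\mathrm{POM} + C_\mathrm{LDPE}.$$

Every sorbed term can equivalently be expressed on the solid-phase basis
(µg per kg of phase, written with a star): $C_x = C^*_x\,[x]$ with
$[x]$ the phase mass concentration in kg/L. At equilibrium
$C^*_x = K_x\,C_w$ with $K_x$ the phase–water partition coefficient in
L/kg. Both bases appear throughout the package and every function
documents which one it uses.

### Partition-coefficient estimation

A POM strip with known $K_\mathrm{POM}$ anchors the freely dissolved
concentration, $C_w = C^*_\mathrm{POM}/K_\mathrm{POM}$. In a closed
spiked tube the balance
$C_\mathrm{init} = C_w\,(1 + K_\mathrm{POM}[\mathrm{POM}] +
K_\mathrm{micelle}[\mathrm{micelle}] + K_\mathrm{oil}[\mathrm{oil}])$
has a unique rearrangement for the one unknown coefficient, which is
what `estimate_k_micelle()` and `estimate_k_oil()` implement. The
estimators are exact inverses of the forward balance, a property the
test-suite exercises as a round trip. Negative estimates — possible
when measurement noise drives the sampler reading above what the spike
supports — are flagged, never clipped, so that noisy synthetic runs
retain their diagnostics. Bovine serum albumin is not a modelled phase;
any sorption to it is absorbed into the operational micelle
coefficient, keeping fidelity to the mass balance above.

Partition coefficients across a homologous chemical series are
summarised by log-linear free-energy relationships,
$\log_{10} K = a \,\log K_\mathrm{OW} + b$, fitted by ordinary least
squares (`fit_loglinear()`, with per-level and pooled fits via
`fit_loglinear_groups()`).

### Digestion kinetics

FFA liberation follows the saturating first-order law
$\mathrm{FFA}(t) = \mathrm{FFA}_{max}\,(1-e^{-k_\mathrm{FFA} t})$, the
unique first-order model with exponential approach to a finite plateau.
`fit_ffa()` estimates both parameters by nonlinear least squares
(Levenberg–Marquardt), initialised at the observed maximum and the
reciprocal half-rise time, with a multi-start sweep over
$k_\mathrm{FFA} \in 10^{[-3,\,1]}$ as a fallback — sparse sampling in
the first two hours of a digestion experiment makes the rate constant
the fragile parameter. The shipped presets
(`enzyme_digestion_params()`) are $10.53\ \mu M$, $0.079\ h^{-1}$ for
the high enzyme-activity treatment and $1.18\ \mu M$, $1.22\ h^{-1}$
for the low treatment; the low-activity rate constant is reproduced as
fitted even though it is acknowledged to be poorly identified.

The pH route (`ph_to_ffa()`, one proton per liberated FFA) ignores
buffering by protein and bile salts and is provided as the assay's
stated proxy; when a direct FFA measurement exists it should be
preferred.

Stoichiometry couples the pools: each FFA adds
$\mathrm{MW}_\mathrm{FFA} \cdot 10^{-9}$ kg/L to the micelle pool and
each three FFA consume one triglyceride,
$[\mathrm{oil}]_t = [\mathrm{oil}]_0 - \tfrac{\mathrm{FFA}(t)}{3}
\mathrm{MW}_\mathrm{oil}\cdot 10^{-9}$. The triglyceride molecular
weight defaults to the glycerol-backbone relation
$\mathrm{MW}_\mathrm{oil} = 3\,\mathrm{MW}_\mathrm{FFA} + 38.05$ g/mol
with oleic acid (282.46 g/mol) as the default fatty acid, both
overridable when a measured fatty-acid composition is available.

### Exchange dynamics

Micelles, oil, water and POM equilibrate much faster than the polymer,
so they form one instantaneously equilibrating pool whose freely
dissolved share is

$$f_w(t) = \frac{1}{1 + K_\mathrm{micelle}[\mathrm{micelle}]_t +
  K_\mathrm{oil}[\mathrm{oil}]_t + K_\mathrm{POM}[\mathrm{POM}]}.$$

The LDPE–water exchange is rate-determining and biphasic: a fast
surface/amorphous reservoir (fraction $f_1$ of plastic-bound chemical)
with uptake $k_1$ and desorption $k_2$, and a slow intrapolymer
reservoir ($k_3$). On the system-volume basis,

$$\frac{dC_\mathrm{LDPE,fast}}{dt} = k_1 C_w - k_2 C_\mathrm{LDPE,fast},
  \qquad C_w = f_w(t)\,\frac{m_\mathrm{pool}}{V_w}.$$

`simulate_exchange()` integrates the chemical masses
$(m_\mathrm{fast}, m_\mathrm{slow}, m_\mathrm{pool})$ with `deSolve`
(lsoda, relative tolerance $10^{-8}$); integrating the pool explicitly,
instead of computing it by difference, makes mass conservation a
genuine check on the solver. Events — one strip removed at each
scheduled time, carrying its proportional share of LDPE mass and
LDPE-bound chemical — are applied as exact discrete maps between
integration segments, so stored values are independent of the output
grid. Solid-basis concentrations are continuous across an event;
system-basis $C_\mathrm{LDPE}$ drops by the removed share.

Three numerical choices deserve note. First, the rate constants act on
system-volume concentrations; this matches the magnitudes the model is
fitted with ($k_1$ spans roughly $10^2$–$10^7\ h^{-1}$ across a PCB
series while $k_2$ stays of order 1), and makes the whole-polymer
distribution coefficient $K_P = k_1/(k_2 [\mathrm{LDPE}] f_1)$
(`derive_kp()`; the fast-reservoir coefficient scaled by $1/f_1$). A
consequence worth knowing: after a strip removal the *remaining* strips
re-load toward the volume-basis equilibrium, so their per-kg
concentration rises — the model's account of why sampled strips show
concentration increases beyond digestion alone. Second, the slow
reservoir is frozen by default: with an intrapolymer half-life of
weeks (default $k_3 = \ln 2/480\ h^{-1}$, a 20-day half-life in the
middle of reported 13–32 day values for thin LDPE) it is inert over a
72 h digestion; `slow_exchange = TRUE` enables it for multi-week
scenarios. Third, the lipase addition dilutes the system (default
factor 8/7 on volume); the configuration stores post-addition values
and the factor only enters the POM-anchored initial condition through
the pre-addition water volume, a numerically negligible term next to
the oil- and micelle-bound mass.

Initial conditions (`initialize_state()`) come from exactly one anchor:
a day-28 sampler reading (the experimental route, with the LDPE load
either measured at $t=0$ or set by the $K_P$ equilibrium), or a total
concentration partitioned at full equilibrium. The plastic-bound mass
is split $f_1 : (1-f_1)$, assuming the two reservoirs equilibrated
during the long pre-incubation. $f_1$ defaults to 0.5; like the default
$K_\mathrm{POM}$ relation (`default_k_pom_relation()`, a labelled
generic substitute for the literature sampler calibration), these are
configuration inputs, not model constants, because their defining
calibrations are external to this package. Over 72 h the trajectory is
insensitive to $f_1$ and $k_3$; both matter only for the solid-basis
normalisation and multi-week extrapolation.

### Inference

`fit_k1k2()` fits only $k_1$ and $k_2$ — everything else fixed — by
Levenberg–Marquardt in $\log_{10}$ space with bounds
$\log_{10}k_1 \in [0, 9]$, $\log_{10}k_2 \in [-4, 2]$, the observed
$t=0$ concentration as the LDPE boundary condition, and the removal
schedule applied exactly as in the experiment. Candidate starts
(including seeds along the $K_P$ ridge, where $k_1/k_2$ is fixed) are
ranked by one cheap forward evaluation and the optimiser runs from the
best, with further starts only on failure. Residuals are unweighted
differences on $C^*_\mathrm{LDPE}$, matching the conventional fitting
choice for such data. Standard errors come from the asymptotic
least-squares covariance in log space, delta-method back-transformed;
Wald p-values mirror conventional significance reporting and are
presentation-only. A flat (equilibrium) series pins only the ratio
$k_1/k_2$: the fit detects near-collinear parameter sensitivities and
flags the result `unidentifiable` instead of reporting meaningless
individual rates.

One identifiability fact shapes what parameter-recovery experiments can
show: with phase compositions like those of the default system,
$k_1 f_w \ll k_2$, so the relaxation rate is essentially $k_2$ and
$k_1$ is identified through the equilibrium amplitude times $k_2$. A
2-hourly sampling grid resolves a $k_2 \approx 1\ h^{-1}$ transient
with about one informative point, so single-series estimates at 5%
measurement noise scatter with a relative spread of roughly 20%
(the asymptotic value for the unweighted estimator), while remaining
nearly median-unbiased across replicates. Recovery tests therefore
check exactness on noiseless data and median bias under noise, not
per-fit precision beyond what the design can support.

## The synthetic-data generator

`scenario_spec()` fixes the emulated study conditions: 10 congeners
evenly spaced over $\log K_\mathrm{OW} \in [5.24, 8.18]$ with spike
totals drawn from 30–124 µg/L; a 0.7 g LDPE (10 strips) / 7 g oil /
~80 mL system; sampling and strip removal at 0, 2, 4, 6, 8, 10, 24,
48, 72 h; quadruplicate systems; digestion truths equal to the
high/low presets above. Generator truths for $K_\mathrm{micelle}$,
$K_\mathrm{oil}$ and $k_1$ are the pooled empirical regressions
(slopes/intercepts 0.99/0.61, 0.85/2.21, and 1.04/−3.01 high or
1.21/−4.28 low). Two quantities have no published generating relation
and are fixed once as realistic constants: $k_2$ truth is 1.0 $h^{-1}$
(high) / 0.15 $h^{-1}$ (low), inside the fitted ranges 0.283–4.36 and
0.087–0.289; and the plastic starts at 10% of its fast-reservoir
kinetic equilibrium (`init_disequilibrium = 0.1`), reflecting a
pre-equilibrated but under-loaded polymer whose digestion-phase
relaxation produces the order-of-magnitude concentration increases
such systems show. Noise is multiplicative lognormal with unit mean on
concentrations (they span orders of magnitude) and additive Gaussian,
floored at zero, on FFA (it does not); the default CV of 0.1 is a
placeholder for unreported replicate variance.

What the generator does *not* emulate: analytical-chemistry artefacts
(GC response factors, detection limits beyond optional left-censoring),
replicate-specific system geometry, buffering in the pH→FFA proxy, and
lipase inhibition by the plastic itself. Passing recovery tests
therefore demonstrate the correctness and statistical behaviour of the
estimation chain under the model's own assumptions — not that those
assumptions hold in any particular lab system.

## Worked example

```{r example, eval = FALSE}
# 1. partition coefficients from noiseless synthetic sampler readings
sp <- scenario_spec(noise_cv = 0)
ds <- make_partition_dataset(sp)
mic <- estimate_k_micelle(ds[ds$experiment == "micelle", ])
fit_loglinear(mic$log_kow, log10(mic$k_micelle))

# 2. digestion kinetics
tt <- c(0, 2, 4, 6, 8, 10, 24, 48, 72)
fit_ffa(tt, ffa_at(tt, enzyme_digestion_params("high")))

# 3. simulate an under-loaded plastic through 72 h of digestion
sys <- gut_system(removal_times = numeric(0))
kp <- kinetic_params(k1 = 9298, k2 = 1,
                     k_micelle = 10^(0.99 * 6.71 + 0.61),
                     k_oil = 10^(0.85 * 6.71 + 2.21),
                     k_pom = 10^predict(default_k_pom_relation(), 6.71))
kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
s0 <- initialize_state(sys, kp, c_total = 80)
s0$m_pool <- s0$m_pool + 0.9 * (s0$m_ldpe_fast + s0$m_ldpe_slow)
s0$m_ldpe_fast <- 0.1 * s0$m_ldpe_fast
s0$m_ldpe_slow <- 0.1 * s0$m_ldpe_slow
traj <- simulate_exchange(sys, kp, s0, tt)
fold_increase(traj)
bioavailability_reduction(traj)
```

## Problem sizes and limitations

The test-suite's simulation studies use 9-point time series, 10-congener
regressions, 200-replicate FFA noise studies, a 1000-replicate
partition-bias study and a 100-replicate rate-recovery study — sizes at
which every Monte-Carlo statement stabilises while the full suite runs
in minutes on a single core.

Known limitations: the model treats the gut as a single well-mixed
batch compartment (no lumen absorption, no multi-segment transit, no
particle translocation); the volume-basis rate law means uptake does
not scale down with remaining plastic mass after removals, which is
faithful to the fitted model but should be remembered when
extrapolating to very small plastic loads; the scenario metrics
(`fold_increase()`, `bioavailability_reduction()`) depend strongly on
measured initial conditions, so the package checks their machinery
(conservation, closed-form agreement, fixed points) rather than any
particular published magnitude; and all defaults standing in for
external calibrations ($K_\mathrm{POM}$, $f_1$, $k_3$) are documented
substitutes that quantitative work should replace.
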