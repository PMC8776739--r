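---
title: "Modelling diatom competition and strain selection under metal stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diatom competition and strain selection under metal stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsel)
```

## The model

`compsel` implements a deterministic *competition-selection* model for
phytoplankton ensembles under toxic stress. The fitness proxy is the
specific exponential growth rate

$$\mu = \ln(D_{t_1}/D_{t_0}) / (t_1 - t_0) \quad [\mathrm{day}^{-1}],$$

measured under nutrient-replete semicontinuous cultivation. A 72 h acute
dose-response assay gives each strain a standardized (0-1) inhibition
coefficient $I_{MC}$ for metal $M$ at exposure concentration $C$, and the
growth rate under exposure is

$$\mu_{MC} = \mu\,(1 - I_{MC}).$$

Strains grow independently and exponentially, $D_t = D_0 e^{\mu_{MC} t}$ —
the model's central assumption is the *absence* of competitive interaction:
strains and species do not modulate each other's growth or the metal's
toxicity. Competition and intraspecific selection are then pure differential
exponential growth. The state variable is the relative density

$$RD_{i,t} = \frac{D_{0,i}\,e^{\mu_{MC,i} t}}{\sum_j D_{0,j}\,e^{\mu_{MC,j} t}},$$

which reduces to the share of exponential terms when all starting densities
are equal (the designed experimental condition; the $D_0$-weighted form is a
strict superset for unequal inocula). The population-level growth rate of a
species is the relative-density-weighted mean of its strains' rates,

$$\mu_{Pop,t} = \sum_i RD_{i,t}\, \mu_{MC,i},$$

a deterministic Fisher-type quantity: it can only rise with time, towards
the rate of the fittest strain, because selection re-weights a fixed set of
rates. The notation leaves open whether the weighted rate should be the
baseline $\mu$ or the inhibited $\mu_{MC}$; the package defaults to
$\mu_{MC}$ (the realized growth rate of the treated population, the curve an
observer would measure), and `population_mu(weight = "mu")` exposes the
alternative. The two coincide in the control.

### Dose-response curves

Inhibition coefficients come from Weibull sigmoids on the log-concentration
scale, in the two standard orientations used by growth-inhibition software:

* W1: $f(x) = c + (d-c)\exp(-\exp(b(\ln x - \ln e)))$
* W2: $f(x) = c + (d-c)(1 - \exp(-\exp(b(\ln x - \ln e))))$

with $(c, d) = (0, 1)$ in the default normalized mode (responses divided by
the mean control response before fitting). A monotone-decreasing (toxic)
curve requires $b > 0$ for W1 and $b < 0$ for W2; fits that come out
increasing over the observed range are rejected with a diagnostic rather
than silently accepted, because only inhibitory responses are meaningful
inputs to the selection model. Hormesis (growth stimulation at low dose) is
deliberately not modelled: a monotone fit underestimates inhibition for
such strains, and this is documented behaviour, not an error.

Concentration 0 (the control) is always evaluated as the analytic limit of
the curve — for a valid decreasing fit this equals the upper asymptote $d$ —
never via $\ln 0$.

$EC_x$, the concentration inhibiting growth by $x\%$, inverts the fitted
curve in closed form (`ecx()`); a bisection inversion of the forward curve
is used as an independent oracle in the test suite, and the two agree to
$10^{-8}$ relative. The conventional family assignment for these metals
(W1 for Cd, W2 for Ag and Cu) is available as `family = "auto"` in
`fit_all_dose_responses()`.

**Fitting choices.** Estimation is Levenberg-Marquardt nonlinear least
squares (`minpack.lm::nlsLM`) with a multi-start grid on the shape,
$|b| \in \{0.5, 1, 2, 4\}$, and the geometric mean of the positive doses as
the starting scale $e$; the converged start with the smallest residual sum
of squares is kept. Convergence tolerances are tightened
(`ftol = ptol = 1e-15`) so that noiseless generate-then-fit round-trips
recover $(b, e)$ to $10^{-6}$, which the tests assert. A fit requires at
least four distinct concentrations including a control; constant responses
(no inhibition signal, $e \to \infty$) and all-start non-convergence fail
with explicit diagnostics.

### Semicontinuous cultivation and numerical choices

`simulate_semicontinuous()` integrates piecewise-exponential densities on an
event grid (daily by default) with serial dilution at scheduled days — all
strains diluted by the same factor, either a fixed factor in $(0, 1]$ or a
reset of the total to its initial value (never concentrating). Because the
factor is common, relative densities are invariant to any dilution schedule
until an extinction occurs; this invariance is a property test. Densities
reported on a dilution day are pre-dilution values, matching sampling "in
connection with dilution".

Numerical safeguards:

* relative densities are computed as a max-shifted softmax, so horizons up
  to $10^4$ days do not overflow;
* a strain crossing the detection limit (default 1 cell mL$^{-1}$) is
  flagged extinct at its *analytic* crossing time within the segment (the
  piecewise-exponential crossing has a closed form) and contributes zero
  afterwards;
* with chronic drift (below) the growth-rate integral is evaluated by
  trapezoid on substeps of 0.01 day, exact for the linear-in-time rate
  except in the substep where clamping kinks it.

The default clamping policy restricts inhibition coefficients to $[0, 1]$
before use (`clamp01`), mirroring a model formulated on standardized
coefficients that cannot predict negative growth. The alternative
`allow_negative` policy propagates raw coefficients, and is the tool for
quantifying how much of an observed decline a clamped model necessarily
misses (inhibition above 1 was in fact observed under Ag in the study this
package is patterned on).

## What the synthetic generator emulates

`generator_config()` encodes the study conditions as defaults:

| parameter | default | meaning |
|---|---|---|
| `n_strains` | 4 per species | ensemble size |
| `mu_mean`, `mu_sd` | SM 1.55 ± 0.12, TB 0.55 ± 0.31 day⁻¹ | species-level growth distributions |
| `exposure` | Ag 0.046, Cd 5.5, Cu 9.7 μM | species-average EC50 exposure concentrations |
| `family` | Cd W1; Ag, Cu W2 | dose-response family per metal |
| `noise_sd` | 0.05 | Gaussian SD of relative plate response |
| `counting_target` | 200 cells per species | microscopy effort per sample (`Inf` = exact enumeration) |
| `obs_days`, `dilution_days` | 0/4/7/10 and 4/7 | observation and dilution schedule |
| `detection_limit` | 1 cell mL⁻¹ | extinction threshold |
| `initial_density` | 500 cells mL⁻¹ per strain | equal-inoculum start |
| `biomass_per_cell` | SM 200, TB 1600 μm² | cylinder-geometry surface area per cell |

Strain growth rates are drawn from the species normal distributions,
truncated below at 0.01 day$^{-1}$ to avoid degenerate non-growing control
strains. Per-metal curves are drawn by sampling the strain's true inhibition
at the exposure concentration uniformly from a per-species range (chosen to
span the tolerance contrasts the two species actually show: SM sensitive to
Ag and tolerant to Cd, TB the reverse, both broadly variable for Cu) and a
log-normal shape magnitude around 2; the scale $e$ is then solved from the
drawn inhibition, so the ensemble spans the intended range by construction.

Counting noise is a single multinomial allocating the total counting effort
(200 cells × number of species) across species in proportion to latent
abundance — the closest tractable model of enumerating a fixed number of
cells per sample — rescaled to cells mL$^{-1}$ against the latent total.
Chronic toxicity, where the paper-scale phenomenon is a growth rate that
keeps falling over days of exposure, is modelled minimally as a linear
drift, $I(t) = I_{72h} + \delta t$ (clamped per policy); the generator
injects it per species and metal, and a recovery test verifies that the
estimated between-interval inhibition increase equals $\delta \,\Delta t$
between interval midpoints. Replicate bottles differ only in counting noise
by default; an optional log-normal bottle effect (`bottle_sd`) exists and
defaults to 0 because the source experiment gives no basis for a value.

**What the generator does not emulate:** fluorometer response curves,
Lugol-fixation losses, aggregated or spatially structured counting error,
nutrient drawdown, allelopathy, or any strain-strain interaction. Passing
recovery tests on synthetic data therefore validates the estimation
pipeline under the model's own assumptions; they cannot detect violations
of those assumptions (interaction, acclimatization, nonlinear chronic
responses) in real data.

## Observational analysis choices

Interval growth rates apply the $\mu$ definition to dilution-corrected
densities: post-dilution abundances are multiplied back by the cumulative
fold-dilution factors (supplied per treatment) so rates reflect true
growth. Endpoints below the detection limit give a missing rate with an
extinction flag, never an exception — a species diluted to extinction is an
expected outcome, not a data error.

Per-replicate inhibition compares each treatment bottle to the *mean*
control rate of the same species and interval by default; strict
replicate-to-replicate pairing is available (`pairing = "replicate"`) since
the bottle pairing of the source design is not recorded in the data layout
this package consumes. The summary table reports per-interval means with
replicate SDs and an "Average" row per species and metal — the unweighted
mean of the interval means, which is the reading consistent with the
published per-metal averages (an alternative reading, a replicate-level
whole-period mean, is not what the printed values arithmetic to). Full
precision is kept internally; display rounding to 2 significant figures is
left to the caller.

The square-root transform offered for group comparisons rejects negative
values with an explicit error: inhibitions above 1 transform fine, but
growth *stimulation* (negative inhibition) has no principled square root
and silently imaginary values would be worse than a refusal.

## Problem sizes used in the validation suite

The package's stochastic guarantees are exercised at these scales, chosen
to give stable Monte-Carlo estimates while keeping the full suite fast:

* dose-response recovery: 200 seeded plates (6 doses × 3 replicates,
  response SD 0.05); fitted EC50 within 20% of truth in ≥ 95% of plates;
* counting-noise recovery: 100 seeded co-culture realizations (200-cell
  counting, 3 bottles, days 0/4/7/10); mean estimated interval inhibition
  within 2 SE of the latent-model truth, evaluated for the
  species × treatment combination whose counts stay above detection
  throughout (S. marinoi under Cd) — the control's inferior competitor is
  excluded below countable densities by day 7, exactly as in the real
  experiment, so its late-interval control rate is unobservable by design;
* ensemble-variability property: 500 seeded strain draws for the
  CV ordering between species.

## Known limitations

* Growth is density-independent: no logistic/Monod saturation, no nutrient
  competition, no chemostat dynamics. The model is only valid for cultures
  held in exponential growth by dilution.
* Strain parameters are fixed over the run except for the optional linear
  chronic drift; acclimatization (inhibition *decreasing* with time) can be
  represented by a negative drift but has no dedicated mechanism.
* The strain-resolved projections of the original study (e.g. which strain
  dominates its species by day 10) require that study's per-strain
  supplementary parameter table; the package reproduces them only when such
  a table is supplied via `read_strain_table()` — the bundled data cover
  species-level summaries only.
* Hormetic dose-response shapes are out of scope; affected strains get a
  monotone fit that understates low-dose performance.

## A worked control-treatment example

```{r example, eval = FALSE}
library(compsel)

gr <- published_species_summaries()$growth
strains <- tibble::tibble(
  strain_id = c(paste0("SM_", 1:4), paste0("TB_", 1:4)),
  species   = rep(c("SM", "TB"), each = 4),
  mu        = rep(gr$mean, each = 4))

sh <- species_share(strains, times = 0:10)
subset(sh, species == "SM" & share > 0.99)
# first whole day above 99%: day 5

traj <- simulate_semicontinuous(competition_scenario(strains))
attr(traj, "extinct")
# the slower species is diluted below 1 cell/mL on day 7
```
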