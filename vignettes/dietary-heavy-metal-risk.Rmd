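---
title: "Probabilistic dietary heavy-metal risk assessment with dietrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic dietary heavy-metal risk assessment with dietrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietrisk)
```

## The problem

Rice is the staple food across South Asia and readily accumulates cadmium,
arsenic and lead from soil and irrigation water. A market-basket survey
measures contaminant concentrations in commercial rice; the public-health
question is what those concentrations mean for the people eating it — on
average, at the upper tail of the exposure distribution, and for vulnerable
groups (toddlers, preschoolers, children, women) whose intake-to-bodyweight
ratio is high. `dietrisk` implements the standard deterministic risk
arithmetic and wraps it in a seed-reproducible Monte Carlo engine so that
the full exposure distribution, not just a point estimate, is reported.

## Model and assumptions

**Exposure.** EDI = CF·IR·EF·ED/(BW·AT) in µg/kg bw/day. The chronic-intake
factor EF·ED/AT defaults to 1 (EF = 365 d/yr, AT = ED·365 d), the usual
convention when the assessment horizon equals the exposure duration; all
three are configurable per population group.

**Risk.** HQ = EDI/RfD per element; HI sums HQs *draw-wise*, so HI
percentiles describe the distribution of the summed hazard rather than a
sum of percentiles. CR multiplies the intake, converted to mg/kg bw/day,
by an oral slope factor in (mg/kg bw/day)⁻¹; TCR sums CRs draw-wise.
Threshold comparisons are strict: HQ/HI flag above 1, CR/TCR are negligible
below 10⁻⁶, acceptable inside [10⁻⁶, 10⁻⁴], unacceptable above 10⁻⁴, and a
value exactly on a boundary is compliant. Copper has no slope factor and is
excluded from the carcinogenic family (with a logged notice).

**Slope-factor units.** The bundled table uses the USEPA oral slope factors
As 1.5, Cd 6.1, Pb 8.5 × 10⁻³ (mg/kg/day)⁻¹. Secondary sources sometimes
typeset all three with an extra 10⁻³; that reading is inconsistent with the
published mean risks this parameterisation reproduces (e.g. a mean arsenic
intake of 0.250 µg/kg bw/day gives CR = 0.250 × 10⁻³ × 1.5 = 3.75 × 10⁻⁴),
so the package adopts the standard magnitudes and documents the choice here
and in `tox_defaults()`.

**Concentration model.** Survey summaries report a geometric mean (GM) with
an arithmetic SD and an observed range. `fit_lognormal()` fits the lognormal
with log-location µ = ln GM and log-scale σ solving
sd² = (e^{σ²} − 1)·e^{2µ+σ²}, by monotone root-finding (the right-hand side
is strictly increasing in σ, so the root is unique; a solution exists for
every sd > 0). Reading the "±" value as an *arithmetic* SD is forced by the
data: for Cd, Pb and Cu the SD exceeds the GM, which no geometric SD can.
One national concentration model is shared by all consumer groups, the
standard design when market samples cannot be assigned to consumers; group
differences are therefore pure IR/BW effects.

**Monte Carlo engine.** Each iteration draws CF (from the fitted lognormal,
or by bootstrap resampling of observed values — both modes are provided
because either is defensible when the original analysis did not say which
it used; `"fitted"` is the default), IR and BW (point values or
distributions, drawn independently: no joint IR–BW model is available), and
evaluates the intake equation. Within a group the same IR/BW stream is used
for every element, so draw-wise sums (HI, TCR) keep the within-person
correlation induced by body size. Percentiles use one fixed rule — sorted
draws with linear interpolation between order statistics
(`stats::quantile` type 7) — chosen for cross-implementation
reproducibility. Default 10,000 iterations; below 1,000 a warning notes
that P99.9 estimates are unstable.

**Seeding.** One integer seed governs every stream. Each
(stratum, element, purpose) stream derives its own sub-seed by hashing the
labels with the master seed (FNV-1a), so adding a stratum or group never
reshuffles existing draws, and reruns are byte-identical.

## The synthetic-data generator

The bundled targets (`nepal_table1()`) are the published GM/SD/range cells
of a 170-sample, seven-province commercial rice survey (sample sizes 49,
20, 27, 13, 35, 10, 16). The raw per-sample data were never deposited, so
`generate_samples()` emulates them: per stratum × element it fits the
lognormal above and draws `n` concentrations. Optional truncation to the
printed range uses rejection sampling but is off by default, because
truncation perturbs the matched moments and the generator's documented
contract is the moment match.

What the generator reproduces: the marginal lognormal shape, the per-cell
GM and arithmetic SD, and the survey's stratification and sample sizes.
What it does not: any spatial or geochemical structure behind province
differences, correlation between elements within a grain sample, or
measurement error and detection-limit censoring (all printed minima are
above the method detection limits, so no censoring machinery is included).
Tests passing on synthetic data therefore validate the *pipeline
arithmetic and distributional logic*, not any claim about real Nepalese
rice beyond what the published summaries carry.

A sampling-error caveat worth knowing: for the most skewed cells
(sd/GM up to 1.8, log-scale σ ≈ 0.9) the relative standard error of a
10,000-draw sample SD is 3–4%, so a recovered SD can sit several percent
from its target at a given seed even though the fitted distribution's
*analytic* SD matches to six significant digits (which the test suite
verifies directly).

## Exposure-factor assumptions

The original survey's intake-rate and body-weight appendix was not
republished, so the bundled groups (`nepal_groups()`, and the YAML config
at `nepal_config()`) are package assumptions, stated as such: a national
adult at IR 0.32 kg/day and BW 60 kg — consistent with Nepal's ~3.65 Mt
annual rice consumption and with the published national mean intakes
(EDI ≈ E[CF]·IR/BW) — and plausible women/children/preschooler/toddler
values chosen once to preserve the reported ordering of vulnerable-group
exposure (preschoolers > toddlers > children > women). Replace them with
survey-specific values via `population_group()` or the config file for any
serious application.

## Worked run

```{r fit}
fit <- assess_risk(nepal_table1(), groups = nepal_groups()["national"],
                   iterations = 10000, seed = 1)
fit
```

```{r table}
tab <- summary(fit)
knitr::kable(tab[tab$metric %in% c("HQ", "HI", "TCR"), ], digits = 3)
```

```{r shares}
lapply(risk_shares(fit), round, 3)
```

Arsenic dominates the hazard index; cadmium dominates the total
carcinogenic risk — the qualitative picture the percentile table quantifies
tail by tail. MAC screening (`screen_mac()`) flags samples strictly above
the FAO/WHO limits; on synthetic national data the only plausible
exceedance is copper, whose printed maximum (10,059 µg/kg) sits just above
its 10,000 µg/kg limit.

```{r plot, fig.width = 6, fig.height = 4}
plot(fit, which = "hi")
```

## Numerical choices and degenerate inputs

- Root-finding tolerance 10⁻¹² (relative) on σ; `sd = 0` short-circuits to
  a point mass at the GM.
- Rejection sampling for truncation aborts after 1,000 sweeps if the bounds
  admit essentially no mass, rather than looping forever.
- Point-mass inputs collapse the simulation exactly: every draw equals the
  deterministic `edi_point()` value and all percentiles coincide.
- Zero concentrations are a hard error in summaries (the geometric mean is
  undefined); negative concentrations are rejected at ingest with row
  numbers.
- Contribution shares require a positive total; an all-zero metric family
  has no defined split.

## Problem sizes

The shipped tests and the reproduction script use 10,000 Monte Carlo
iterations per group × element (the conventional size for P99.9 reporting,
and the size used throughout the package's own analyses), 10,000-draw
parameter-recovery checks per summary cell, and one 10⁶-draw spot check of
the moment match. A full five-group national assessment at 10,000
iterations runs in well under a minute on a single core.

## Known limitations

- Linear, slope-factor dose–response only; no speciation (e.g. inorganic
  arsenic fraction), no toxicokinetics.
- No correlated inputs: elements are independent given the stratum, IR and
  BW are independent of each other and of concentration.
- One food item: no total-diet aggregation across commodities.
- The acceptability thresholds (HQ/HI 1; CR 10⁻⁶–10⁻⁴) are conventions,
  configurable but not defended here.
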