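---
title: "The SADC-WC stock-and-flow model: structure, calibration and scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SADC-WC stock-and-flow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadcwc)
```

## The system being modelled

Substance abuse and drug-related crime in the Western Cape province of
South Africa behave as a *syndemic*: two mutually reinforcing epidemics
embedded in the same community. `sadcwc` implements the SADC-WC
(substance abuse and drug-related crime, Western Cape) system-dynamics
model of that syndemic as a five-stock compartmental model over calendar
time:

| Stock | Meaning | Unit |
|---|---|---|
| `C` | community at risk | persons |
| `D` | substance abusers and participants in drug-related crime | persons |
| `S` | persons in correctional services | persons |
| `R` | persons in specialist rehabilitation | persons |
| `L` | open drug-related crime cases held by law enforcement | cases |

`L` is a *case ledger*, not a count of persons: the conservation law of
the model covers `C + D + S + R` only.

Sixteen flows connect the stocks (see `sadcwc_flow_table()`). The
governing equations are

$$
\begin{aligned}
\dot C &= (bC + m) + sr\,R + sc\,S + se\,D - dC - \iota \\
\dot D &= \iota + rR - u(t) - s\,c\,L - se\,D - dd\,D \\
\dot S &= s\,c\,L - \rho - sc\,S - sd\,S \\
\dot R &= u(t) + \rho - sr\,R - rR - rd\,R \\
\dot L &= \kappa(t) - fc\,L - s\,c\,L
\end{aligned}
$$

where $\iota$ is the initiation flow, $\rho$ the correctional-referral
flow, and $u(t)$, $\kappa(t)$ the two exogenous drivers (rehabilitation
uptake and new crime cases). Parameters and their defaults are
documented in `?sadcwc_params`; the three criminal-justice fractions
($c = 0.25$ of cases reach court, $s = 0.25$ of those convict,
$fc = 0.75$ fail) and the demographic rates are published point values,
while the initiation/self-conviction rates ($di, ci, se \in
[0.05, 0.10]$) and excess death rates ($dd, rd, sd \in [0.015, 0.020]$)
carry only declared ranges and default to midpoints.

The sentence-completion rate $sc$ is derived, not assumed: with 31% of
offenders serving a median of 2.5 years, 42% of 10, 10% of 12.5 and 16%
of 30, the proportion-weighted sum of reciprocal medians gives

```{r sc-rate}
successful_corrections_rate(
  sentence_mix(c(0.31, 0.42, 0.10, 0.16), c(2.5, 10, 12.5, 30)))
```

i.e. 0.179/yr. The printed proportions sum to 0.99 (rounded
percentages); they are used as printed, and `sentence_mix()` accepts a
sum-to-one deviation of up to 0.015 for exactly this reason.

## Flow-form choices

The published converter table is internally inconsistent in four places;
the package resolves each on substantive grounds, keeping the rejected
form behind a switch where that is useful:

* **Initiation.** The table prints the bilinear product
  $di\,CD + ci\,CD$, which at the published magnitudes
  ($C \approx 4.6\times 10^6$, $D \approx 7\times 10^5$) yields
  $\sim 10^{11}$ persons/year. The default is the frequency-dependent
  form $(di + ci)\,CD/N$ with $N = C+D+S+R$, the standard interaction
  term of the drug-epidemic literature this model descends from.
  `initiation_form = "bilinear"` restores the raw product.
* **Convictions.** "Convictions" and "successful convictions" are both
  printed as $c\,L$, yet the initial correctional stock is computed as
  $L_0 \times 0.25 \times 0.25$ and the source texts state that only a
  quarter of the quarter of cases reaching court convict. The flow into
  `S` (and out of `D` and `L`) is therefore $s\,c\,L$; failed
  convictions stay at $fc\,L$.
* **Correctional referrals.** The flow runs S → R but is printed with
  magnitude $cc\,R$. We keep the printed magnitude
  (`referral_base = "R"`): it is what reproduces the reported behaviour
  of the system — referrals stay an order of magnitude below uptake,
  and rehabilitation only roughly doubles over the projection. The
  source-stock convention $cc\,S$ (`referral_base = "S"`) makes
  referrals comparable to uptake and inflates `R` well beyond the
  reported trajectory.
* **Sentence completion.** Printed as $sc\,C$, but the flow runs S → C;
  $sc\,C \approx 8\times10^5$/yr would drain a stock of $\sim 2000$
  instantly. Implemented as $sc\,S$.

One person, one case: a successful conviction simultaneously moves a
person D → S and closes a case out of L. The flow table therefore holds
two records (`convictions`, `successful_convictions`) sharing the value
$s\,c\,L$, and the engine's limiter caps the person-side flow at what
`D` can supply.

The initial state is the published 2004 configuration
(`sadcwc_initial_state()`): population 4,645,600; `D` at 15% of it
(696,840); 30,432 open cases; 4,563 in rehabilitation;
`S` = 30,432 × 0.25 × 0.25 = 1,902. The published table sets `C` to the
*full* population although `D` is carved out of the same total;
`disjoint = TRUE` removes the overlap, but the published convention is
the default.

## Exogenous drivers

Two converters are data-driven rather than equation-driven, and their
underlying annual series are not published; the package reconstructs
them from their printed anchors (`build_uptake_series()`,
`build_cases_series()`):

* **Uptake** (admissions to rehabilitation, D → R): anchored at 4,563
  (2004) and 7,195 (2013), geometrically interpolated and extrapolated
  at the implied mean growth, $(7195/4563)^{1/9} - 1 \approx 5.2\%$/yr.
* **Cases** (new drug-related cases, → L): a geometric series from the
  2004 base of 30,432. The province's own annual growth is unpublished;
  the default rate is the one implied by the national arrest counts,
  $(82062/19940)^{1/9} - 1 \approx 17.0\%$/yr, and it is a calibration
  target (below).

Geometric rather than linear growth was chosen because the historical
window is described as exponential growth throughout; `growth_model =
"linear"` is available. The exact annual values the original STELLA
implementation used are unrecoverable, and every downstream trajectory
number inherits that uncertainty.

## Numerical engine

`integrate_stocks()` is a fixed-step integrator in the system-dynamics
tradition: explicit Euler with `dt = 1/12` year by default (fixed-step
monthly stepping is the convention of STELLA-style engines; the original
publication does not state its integrator or step), with classical RK4
available for convergence checks — on the exponential test problem the
Euler error halves with the step while the RK4 error falls
sixteen-fold.

Negative stocks are prevented by *proportional outflow limiting*: at
each step (and each RK4 stage), if a stock's total outflow over `dt`
exceeds its level, all its outflows are scaled by the common factor
`level/(outflow × dt)`; inflows are untouched, so limiting cannot
create or destroy mass — closed subsystems are conserved to machine
precision per step. Under Euler this makes every trajectory point
non-negative for arbitrary non-negative rates; under RK4, stage mixing
can undershoot by round-off, which a final clamp at zero absorbs.
Non-finite flow values abort with the offending flow's name and time.
Reporting is always on annual snapshots regardless of `dt`.

## Calibration

The estimated parameters were originally tuned by hand until the system
"behaved as expected". `calibrate()` formalises that as bounded
least-squares: minimise the sum of squared *relative* errors (the
stocks span $10^3$–$10^6$, so absolute errors would be dominated by
`C`) over anchor observations, with every free quantity confined to its
declared range. The default free quantities are the combined initiation
rate `init_total` $= di + ci \in [0.10, 0.20]$ (split equally between
`di` and `ci`), the self-conviction rate `se` $\in [0.05, 0.10]$, and
the case-series growth rate $\in [0, 0.35]$.

The default anchor set (`default_calibration_anchors()`) pins the model
to every published number available: `R` = 4,563 (2004) and 7,195
(2013); `L` = 30,432 (2004) and 30,432 × 4.115 (2013, the national
arrest growth factor applied to the provincial base); plus the reported
relation that the abuser stock runs at about ten times the open case
load by the end of the historical window, encoded as a ratio anchor
`D/L` = 10 at 2014. The ratio anchor is essential for identifiability:
the L → S → R chain contains no `C` or `D` term, so level anchors on
`R` and `L` alone are *flat* in `di`, `ci` and `se`. Even with a `D`
anchor, only the combination $(di{+}ci)\,\overline{C/N} - se$ is
strongly identified; `se` separates from `init_total` only through the
slow drift of $C/N$ along the trajectory. Parameter-recovery tests
therefore anchor all five stocks, under which noiseless refits recover
the generating values to machine precision.

The search is deterministic by design (reproducibility over speed): a
full factorial grid over the box (7 points per dimension by default)
followed by box-constrained quasi-Newton refinement (`nlminb`, run
twice, with the absolute-convergence tolerance disabled — near-perfect
fits have losses near zero and the default tolerance would stop the
iteration prematurely). No randomness enters anywhere, so a `seed`
argument exists only for interface uniformity.

## Scenarios and interventions

`run_scenario()` simulates a `scenario_spec()`: the hindcast (2004–2014),
the baseline projection (2004–2019, exogenous series extrapolated at
their historical growth), and three interventions, each a linear ramp
over 2014–2019 held constant thereafter (`make_intervention()`):

1. court fraction `c` and conviction fraction `s` both 0.25 → 0.50;
2. correctional-referral rate `cc` from its baseline 0.057 → 0.10 (the
   intervention is described as ramping from 0.05, but the baseline
   value is 0.057; the ramp starts from the model's actual baseline);
3. relapse rate `r` 0.257 → 0.127.

Ramps alter only the named parameters; the exogenous series stay at
their baseline assumptions, since nothing in the source describes a
feedback from interventions into the recorded case or admission data.
At default parameters the hindcast grows every stock monotonically;
intervention 1 is the only one that materially moves the abuser stock,
while 2 and 3 act through the smallest stock in the system (`R`) and
barely register — the acceptance suite checks exactly these orderings
rather than digitised curve values, which are not published.

```{r interventions, eval = FALSE}
params <- sadcwc_params()
exo <- exogenous_flows()
base <- run_scenario(baseline_scenario(), params, exo)
int1 <- run_scenario(make_intervention(1, params), params, exo)
compare_scenarios(base, int1)
```

## Synthetic observations

`simulate_observations()` produces annual stock snapshots perturbed by
multiplicative log-normal noise, seeded and reproducible — the fixture
generator for parameter-recovery testing. It emulates the *sampling*
noise of annual reporting, not its real pathologies: no under-reporting
trends, no definition changes between reporting years, no correlation
between stocks' errors. Passing recovery tests therefore demonstrate
that the estimation machinery is consistent, not that the real
historical series identify the parameters.

## Problem sizes and tolerances

The shipped tests and the acceptance script run the full published
configuration: monthly steps over 11- to 16-year horizons (132–192
flow evaluations per trajectory), 7³ grid points plus refinement for
the default calibration, 5³ for recovery, 200 random draws for the
non-negativity property and 1000 replicates for the noise-bias check.
Conservation is asserted at 10⁻⁹ relative per step, the RK4 exponential
check at 10⁻⁴ relative, recovery at 5% relative error.

## Known limitations

* The two exogenous series are reconstructions from anchors; any
  quantitative disagreement with the original figures is confounded
  with this.
* The published 2014→2019 abuser-stock growth of about 50% is not quite
  reached under the default calibration (the fit that honours the
  ten-times `D/L` relation yields ≈34%); the bounded initiation rates
  cannot sustain the original's constant-rate exponential growth once
  the susceptible fraction `C/N` starts falling. The discrepancy is
  reported as computed, not tuned away.
* `C` and `D` overlap at initialisation (published convention), so `N`
  slightly overcounts the population.
* No identifiability or posterior analysis is attempted; calibration is
  a bounded point fit. A Bayesian treatment is future work.
* No disaggregation by drug type, district or demographic group, and no
  separate stocks for abuse-only / crime-only / both.
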