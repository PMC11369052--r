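---
title: "Error-induced extinction in multi-type critical birth-death processes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-induced extinction in multi-type critical birth-death processes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critbdm)
```

## The model

`critbdm` studies populations of cells that divide, die, and accumulate
mutations one at a time, under *error-induced extinction* (EEX): the regime
in which every lineage eventually acquires a lethal mutation because the
mutation rate sits at the tolerable limit.  A cell that has accumulated
`i - 1` mutations is a *type-i* cell.  Type `i` divides at rate
$\alpha_i$, dies at rate $\beta_i$, and mutates to type `i + 1` at rate
$\nu_i$, along the consecutive chain $1 \to 2 \to \dots \to n$; type `n`
cannot mutate (its next mutation would be the lethal one, folded into its
death rate).  The process is **critical** when
$\alpha_i = \beta_i + \nu_i$ for every type: each sub-population's
appearance and disappearance rates balance, so extinction is certain, yet
mean counts never decay.  The reference parameterization (`simple_bdm(n)`)
sets every rate involved to one: types `1..n-1` divide or mutate at rate
one, type `n` divides or dies at rate one.  With division rate one, one
time unit is one generation — an interpretation, not an enforced unit.

Three families of quantities are computed, each by at least two
independent routes (closed form, ODE, FFT inversion, simulation), which is
the backbone of the test suite:

* **Survival**: $S_{i,n}(t)$, the probability that any cell is alive at
  $t$ from one type-`i` cell, solves the backwards-coupled system
  $S_i' = S_{i+1} - S_i^2$ (with $S_n' = -S_n^2$), $S_i(0) = 1$.  The
  last component is exactly $1/(1+t)$; for $n = 2$ the first component
  has the closed Bessel form implemented in `two_type_survival()`.  The
  type-presence probability $Q_{i,n}(t)$ (some type-`n` cell alive)
  satisfies the same equations with $Q_i(0) = 0$ for $i < n$,
  $Q_n(0) = 1$.
* **Cell-number distributions**: generating functions are known in closed
  form for one and two types; coefficients are extracted numerically by
  FFT contour integration (`gf_invert()`, `pmf_type2()`).  Conditioned on
  type-`n` survival, $Z_n(t)/t$ has the limit density
  $\chi_n F(1+\chi_n; 2; -y)$ with $\chi_n = 2^{1-n}$, whose tail makes
  the mass function algebraic *and stationary*,
  $P_s \approx \chi_n/\Gamma(1-\chi_n)\, s^{-1-\chi_n}$, on the window
  $t \ll s \ll t^{(n-1)/(1-\chi_n)}$.
* **Arrival and exit times**: $g_{i,n}(t) = P(T_n \le t)$ solves
  $g_i' = -g_i^2 + \nu g_{i+1}$ with $g_n \equiv 1$; for $n = 2$,
  $g = \sqrt\nu \tanh(\sqrt\nu t)$, and the first type-2 cell arrives on
  average at $\log 2$.  The limit $g_{1,n}(\infty) = \nu^{1-\chi_n}$ is
  the law of the maximal type ever reached.  For pure birth-mutation, the
  extinction time of type `n` satisfies $\{E_n > t\} = \{Z(t) > 0\}$
  exactly, which the simulator tests replicate-by-replicate.

The arrival family with constant mutation rate $\nu$ is read as the
critical scheme with death rate $1 - \nu$ per type; the backward-equation
derivation reproduces the quadratic arrival system only under that
reading, which we therefore adopt.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `birth`, `death`, `mutation` | per-capita rates, events per cell per time unit | all 1 / 0 / 1 (scheme) | the unit-rate critical chain; one unit = one generation |
| `reps` | ensemble size | caller-chosen | standard errors scale as `reps^-1/2`; 1e5 puts Monte-Carlo error near 0.3% on order-one means |
| `rtol`, `atol` | ODE tolerances | `1e-10`, `1e-12` | residual-coefficient extraction and cross-checks at `1e-8` need headroom |
| `radius` | inversion contour | 0.99 | see below |
| `max_events`, `max_cells` | SSA safety caps | `1e8`, `1e7` | critical extinction times have infinite mean; caps fail loudly (classed error with the partial trajectory) rather than truncating silently |

Non-critical rate sets are allowed (a validation *warning*, not an
error), because the simulator is exact for any rates; every closed-form
and asymptotic function in the package assumes the critical balance.

## Numerical choices

**Stochastic simulation.** Exact SSA (direct method) only — criticality
keeps populations desk-scale over the horizons of interest, and exactness
is the point; no tau-leaping.  Randomness comes from an in-package
xoshiro256++ generator seeded through splitmix64 from the pair
`(master seed, replicate index)`, so every replicate is an independent,
platform-reproducible substream and ensembles are order-free.  Grid
recording is left-continuous: a grid time coinciding exactly with an
event records the pre-event state.  Extinction times of types still alive
at the horizon are censored: excluded from extinction-time means,
included in survival curves.

**Bessel evaluation.** The two-type closed form is a ratio of modified
Bessel functions at argument $2\sqrt{1+t}$; naive evaluation overflows
near $t \approx 700$.  All evaluations use exponentially scaled $I$ and
$K$ with the scaling cancelled algebraically, stable beyond $t = 10^8$.
On inversion contours the argument is complex; since base R's Bessel
functions are real-only, the package evaluates the scaled integral
representations by midpoint/trapezoid rules, which converge spectrally
here (the `I` integrand is entire and periodic; the `K` integrand is
analytic, even, and exponentially decaying).  All contour arguments
satisfy $|\arg z| \le \pi/4$, where these rules reach near machine
precision — verified against base R on the real axis and via the
Wronskian identity off it.

**Contour inversion.** Coefficients are Cauchy integrals on $|x| = r$,
$r < 1$ because the generating function is singular at $x_2 = 1$.  The
factor $r^{-s}$ amplifies quadrature round-off, bounding the usable
`s_max` at about $15/|\log_{10} r|$; `gf_invert()` computes and enforces
this bound (double precision only — deeper tails need a larger radius,
e.g. `radius = 0.999` reaches `s = 34500`).  Default node count is
`8 * (s_max + 1)`, making aliasing (weight $r^N$) negligible.  Negative
coefficients below `1e-12` are zeroed as round-off; anything worse
raises a quality error rather than being clipped.

**ODE integration.** `lsoda` at `rtol 1e-10 / atol 1e-12` on grids that
may be logarithmic out to $t = 10^8$ or beyond.  Clipping to $[0,1]$
happens only in the returned values, never in the solver state.  The
arrival system is integrated in $g$ rather than $h = 1 - g$: the
quadratic form is better conditioned near the defective limit.  For
extracting the second- and third-order expansion coefficients (1/4 and
3/32) the plain formulation would need ~$10^{-12}$ absolute accuracy at
$t = 10^6$; `survival_penultimate_ode()` instead integrates the rescaled
variable $w = \sqrt{1+t}\,S$ on log-time, which keeps $w = O(1)$ and
resolves the residuals.  The mean arrival time augments the arrival
system with the integral $\int(1-g)$ as an extra state, so the
quadrature inherits the solver tolerances.

**Confluent hypergeometric function.** $F(1+\chi; 2; -y)$ is evaluated
through the Kummer transformation $e^{-y} M(1-\chi, 2, y)$, whose series
has positive terms (no cancellation); beyond $y = 30$ the large-argument
asymptotic branch is used.  For $\chi = 1$ the function is exactly
$e^{-y}$.

**Tail-slope estimator.** The stationary-tail window
$t \ll s \ll t^{(n-1)/(1-\chi_n)}$ is operationalized with factor-5
margins on both sides (`tail_window()`), since no constants attach to
the "much less than".  When a single slope is quoted for a window, it is
the *mean local slope* — total log-drop over log-width between the
endpoints.  A least-squares fit over the same window reads systematically
steeper/shallower, because for accessible times the window edges touch
the crossover at $s \sim t$ on one side and the cutoff
$s_* \propto t^{(n-1)/(1-\chi_n)}$ on the other; even the scaling
function $F(3/2;2;-y)$ itself has least-squares slope $\approx -1.58$
over $y \in [5, 50]$ while its mean local slope is $\approx -1.55$,
converging to $-3/2$.  The cutoff $s_*$ is an order of magnitude only
(the defining consistency argument fixes no constant), and is reported as
such.

## The synthetic ensembles: what they do and do not show

There is no external data: trajectory ensembles generated by the exact
SSA under the unit-rate critical scheme *are* the study conditions, and
the Monte-Carlo estimators (Wilson intervals for survival, standard
errors for means, exact arrival/extinction samples) are compared against
the closed forms and ODE solutions they should reproduce.  Passing tests
therefore show internal consistency of the mathematics and its
implementation — they do not show that any real microbial or tumour
population follows the model.  In particular the generator realizes
exponential waiting times, well-mixed populations, strictly consecutive
mutations and time-constant rates; real colonies violate all four to
varying degrees (cell-cycle structure, spatial growth, parallel
mutational paths, environment-dependent rates), and the model's
death-free types below the last one make "time in generations" exact
only for the no-death scheme.

Problem sizes used by the default test run were chosen to keep
Monte-Carlo error well inside the asserted tolerances at desk scale:
ensembles of 2e4–1e5 replicates for horizons $t \le 10$, 2e4–3e4
replicates to $t \in [20, 50]$, and 2e3–5e3 replicates for the heavier
$n = 3$ comparisons at $t \le 100$ (the expected event count per
replicate grows like $t^n/n!$, which rules out large ensembles at
$n = 4, t = 100$).  ODE-based checks run to $t = 10^{10}$ where needed;
they are effectively free.

## Design choices where the design was open

* **Presence initial conditions**: the condition set
  `Q_i(0) = 0` is applied for *all* `i < n` (the index `i = 1` is forced
  by `Z_n(0) = 0`, so a range starting at `i = 2` would be incomplete).
* **Caps semantics**: "run until extinction" is implemented with event
  and population caps that raise a classed error carrying the partial
  trajectory; a cap is a *statement about the run*, not data, and callers
  can treat capped runs as censored (the test suite does).  Where a
  fixed-length run is wanted, the horizon is `t_max` in time units, with
  the event cap as a separate guard — "steps" in the sense of SSA events
  is exposed through `max_events`.
* **Shannon index**: natural logarithm by default (maximum $\log n$),
  with the base exposed; the ensemble version averages over replicates
  *surviving at each time* and reports how many there were, since the
  index is undefined for an extinct population.
* **Survival-time inversion**: `generations_to_survival()` returns the
  root of the exact/ODE survival; the expansion-based estimate is
  attached as an attribute for comparison, never silently substituted.
* **Exponent naming**: a single exponent family $\chi_n = 2^{1-n}$ is
  exported (`chi_exponent()`); the survival-tail and size-tail exponents
  coincide.

## Known limitations

* Closed forms stop at two types; everything beyond is ODE-based or
  asymptotic (no exact solution exists for $n \ge 3$, and the exact
  $g_{1,3}$ — a lengthy hypergeometric combination — is deliberately not
  implemented; the ODE layer covers it).
* Arrival ODEs assume a constant mutation rate across types;
  fully heterogeneous arrival laws are available only through the
  simulator.
* Only the consecutive mutation chain is supported — no branching
  mutation graphs, no sub- or super-critical intermediate types, no
  spatial structure or carrying capacity.
* Contour inversion is double-precision; its enforced `s_max` bound is
  the honest limit of the method as shipped.
* Second-order expansions are accurate to a few percent only once
  $t \gtrsim 10^2$–$10^3$ for moderate `n`; the third-order term exists
  only for the penultimate-type case.
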