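---
title: "A stage-structured biomass model of a competing, jointly harvested flatfish pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stage-structured biomass model of a competing, jointly harvested flatfish pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flatmix models the joint dynamics of two demersal flatfish stocks — sole
(*Solea solea*) and plaice (*Pleuronectes platessa*) — that compete for
benthic invertebrate food and are caught together by a single,
indiscriminate fishery such as a beam-trawl fleet. This vignette is the
package's account of the model, its parameters, the numerical machinery,
and the design decisions behind both. Everything quantitative stated here
is computed by the package's tests or scripts; nothing is quoted from
elsewhere.

## The model

Each stock is represented by the biomass densities (g per litre of benthic
habitat) of three life stages: small juveniles $J$ (from settlement to the
smallest size retained by the gear), large juveniles $LJ$ (caught but below
the legal landing size, hence discarded), and adults $A$ (caught and
landed). This is the stage-structured biomass approximation of a fully
size-structured population: stage-level net biomass production and a
production-dependent maturation flow stand in for individual growth, and at
equilibrium the approximation is exact.

Three food resources follow semi-chemostat (open-flow) dynamics,
$\mathrm{d}R/\mathrm{d}t = r\,(K - R) - \text{grazing}$: a
plaice-exclusive resource with maximum $K_p$, a sole-exclusive resource,
and a resource shared by both species. The overlap parameter
$\omega \in [0,1]$ splits the non-plaice resource base $K_m$ between the
sole-exclusive pool, $(1-\omega) K_m$, and the shared pool,
$\omega K_m$. At $\omega = 0$ the two stocks are fully decoupled; at
$\omega = 1$ sole feeds only on the shared pool and competes head-on with
plaice, which always retains $K_p$ ($= 3 K_m$ by default, reflecting the
larger plaice habitat).

Every stage $i$ of species $n$ feeds on its exclusive pool $R_n$ and the
shared pool $R_{sh}$ through a Holling type-II functional response with
the two resources entering additively and with equal weight,

$$ IR_{i,n} = I_{\max,i,n}\,
   \frac{R_n + R_{sh}}{R_h + R_n + R_{sh}}, $$

and its intake is split across the two pools in proportion to their
densities. Two design decisions live here: the shared resource carries no
species-specific preference coefficient (none appears in the parameter
set), and "overlap" acts purely through the carrying-capacity split, not
through the functional response. Net biomass production per unit body mass
is assimilation minus maintenance, $\nu = \delta\,IR - T$; a negative
$\nu$ is a starvation loss.

Stage dynamics per species (argument suppressed, $\nu^+ = \max(\nu, 0)$):

$$
\begin{aligned}
\mathrm{d}J/\mathrm{d}t  &= \nu_A^+ A + \nu_J J - \gamma_J J - \mu J,\\
\mathrm{d}LJ/\mathrm{d}t &= \gamma_J J + \nu_{LJ} LJ - \gamma_{LJ} LJ
                            - (\mu + f_{LJ} E)\, LJ,\\
\mathrm{d}A/\mathrm{d}t  &= \gamma_{LJ} LJ + (\nu_A - \nu_A^+) A
                            - (\mu + f_A E)\, A.
\end{aligned}
$$

Adults do not grow: positive adult production is reproduction
($\nu_A^+ A$ enters the juvenile equation), negative adult production is
starvation loss. Maturation out of a stage with entry-to-exit mass ratio
$z$ and total mortality $\mu_{tot}$ is

$$ \gamma(\nu, \mu_{tot}, z) =
   \frac{\nu - \mu_{tot}}{1 - z^{\,1 - \mu_{tot}/\nu}}, \qquad \nu > 0, $$

with $\gamma = 0$ when $\nu \le 0$ (starving stages neither mature nor
reproduce) and the removable singularity at $\nu = \mu_{tot}$ evaluated by
its limit $-\nu / \ln z$; `maturation_rate()` is continuous in $\nu$, which
the tests check on a grid straddling the limit.

The fishery applies one effort $E$ (an arbitrary intensity unit) to both
species at once, modulated by stage- and species-specific catchabilities:
fishing mortality is $f\,E$ on large juveniles and adults, zero on small
juveniles. Landings are the adult catch flow $f_A E A$, discards the
large-juvenile catch flow $f_{LJ} E\, LJ$, and revenue is price times
landed biomass. Because the habitat volume is left implicit, revenue is
reported per litre of habitat per day (EUR L⁻¹ d⁻¹, with the g→kg factor
of 1000 explicit in the code); only the shape of revenue-effort curves is
meaningful, and it is unaffected by the volume convention.

## Parameters

The default parameter set (`default_params()`, mirrored by the shipped
YAML config) is a published North Sea parameterisation. Entries the
package can re-derive are re-derived and validated rather than trusted:

* Stage-boundary lengths (settlement, smallest retained size, landing
  size) are converted to weights by $W = aL^b$ (sole $a=0.0091$,
  $b=3.077$; plaice $a=0.0089$, $b=3.0353$).
* The stage average weight is the logarithmic mean
  $(W_{\max}-W_{\min})/(\ln W_{\max} - \ln W_{\min})$ — the mean of $W$
  under the $1/W$ within-stage density; a quadrature oracle confirms this
  in the tests. The printed form of that formula is ambiguous about
  parenthesisation; the logarithmic-mean reading reproduces the reference
  sole weights to printed precision, the other reading does not.
* Stage mass ratios are $z = (L_{entry}/L_{exit})^b$; the $a$ coefficient
  cancels (property-tested over random $a$).
* $\mu = 0.001\,\mathrm{d}^{-1}$ corresponds to
  $e^{-0.365} \approx 69.4\%$ annual survival.
* The resource maximum 0.3 g L⁻¹ arises from an areal benthos standing
  stock of 10.1 g m⁻² concentrated in one third of the bottom surface
  under a 10 cm benthic water layer (`benthos_to_volumetric()`).

Validation accepts a derived entry within half a unit of the reference's
printed precision or within 2% (sole) / 7% (plaice) relative. Two
documented inconsistencies in the reference table motivate the asymmetry:
the printed plaice weights are not consistent with the printed plaice
length-weight coefficients ($a = 0.0089$ yields an adult weight near 197 g
rather than the printed 208.6 g, a 5–6% gap), and the derived sole
large-juvenile-to-adult mass ratio is 0.1185, which sits half a printed
unit above the printed 0.118. The dynamics always consume the derived,
full-precision weights and ratios; the printed values serve only as
validation references. A further, unresolved oddity is the resource
regrowth rate: dividing the reported benthic productivity by the resource
maximum gives roughly 0.003 d⁻¹, while the table value is 0.1 d⁻¹; the
table value is used as-is.

Non-derivable rates (maximum ingestion $I_{\max}$ per stage, maintenance
$T$, conversion efficiency $\delta = 0.36$, adult catchabilities, prices,
$K$'s, $R_h$, $r$) are consumed verbatim.

### The discard-fraction calibration, and a parameter-table inconsistency

Large-juvenile catchabilities are historically tuned so that the
equilibrium discarded-over-landed biomass fraction matches observed
discarding: 0.3 for plaice, 0.1 for sole, in the absence of competition.
`tune_catchability()` implements this as two independent scalar
root-finds at $\omega = 0$ (the stocks are uncoupled there), each
evaluation re-solving the equilibrium, at reference effort $E = 1$ — the
effort at which the adult catchabilities equal the assessment-derived
daily fishing mortalities, and therefore the natural operating point; the
reference effort is an explicit argument.

Running the calibration check on the default table reveals an
inconsistency: with the shipped $f_{LJ}$ values (5·10⁻⁵ plaice, 2·10⁻⁶
sole) the realized equilibrium fractions at $\omega=0$, $E=1$ are ≈0.072
(plaice) and ≈0.0036 (sole), not 0.3 and 0.1. The discrepancy is
structural, not numerical. At any coexistence equilibrium of this model
the resource density is pinned at the *adult* break-even level
$R^\*$ with $R^\*/(R_h+R^\*) = T/(\delta I_{\max,A})$: adults have the
lowest mass-specific intake, and the tiny juvenile mass ratio $z_J$
(3·10⁻⁴–3·10⁻³) makes the juvenile stage almost lossless, forcing adult
net production to zero at equilibrium. That pins $\nu_{LJ}$, hence
$\gamma_{LJ}$, hence the large-juvenile-to-adult biomass ratio
($\approx 1.8$ for plaice and $\approx 2.6$ for sole at $E=1$) —
independently of the carrying capacities. The shipped $f_{LJ}$ values
would require $LJ/A \approx 7.6$ and $\approx 73$ respectively; the sole
value is unreachable at *any* effort. `tune_catchability()` reproduces
the 0.3/0.1 targets exactly with $f_{LJ} \approx 1.9\times10^{-4}$
(plaice) and $\approx 5.4\times10^{-5}$ (sole), and the package's
acceptance checks report the honestly computed fractions for the shipped
values rather than the nominal targets.

## Computing equilibria

`solve_equilibrium()` integrates the stiff 9-dimensional system
(`deSolve::lsoda`, relative tolerance 10⁻⁸) from a cold seed (resources at
their maxima, 10⁻³ g/L in every consumer stage) or a warm start, in
geometrically growing probe windows, until the relative state change over
a window falls below 10⁻⁸; it then polishes the endpoint with a damped
Newton iteration (central-difference Jacobian, step halving) to a residual
below 10⁻⁹ g L⁻¹ d⁻¹ in max-norm. Non-convergence is flagged on the
record, never silent.

Extinction handling deserves care because every extinction here is a
transcritical exchange with the boundary equilibrium, approached along a
slow manifold:

* A species whose total biomass falls below 10⁻⁹ g/L is clamped to zero
  (the extinct set is forward-invariant) and the remaining components are
  re-polished. A Newton iterate converging to an infeasible interior root
  (negative stage biomass) triggers the same path.
* Classification is then verified against the invasion criterion: the
  dominant eigenvalue of the linearized stage dynamics of the rare species
  at the resident equilibrium (`invasion_rate()`). A species marked
  extinct that could invade is re-seeded and re-polished; a rare,
  slowly-decaying remnant that cannot invade is clamped. Without this
  check, a decaying remnant can slip under the absolute residual floor
  (residual ≈ mortality × biomass) and masquerade as an equilibrium — an
  early development version produced a spurious sole extinction threshold
  this way, detected because at $\omega$-values where plaice is extinct
  the sole threshold must exactly match the $\omega=0$ value (the two
  sole resource pools aggregate to one), which the fixed solver
  reproduces to all printed digits (E* = 1024.03 both ways).

Sweeps (`sweep_effort()`, `sweep_omega()`) use natural-parameter
continuation: each solve warm-starts from the previous equilibrium,
following the branch upward from the unfished state. Pseudo-arclength
continuation is unnecessary — all structures encountered are stable
equilibria and transcritical crossings, with no folds on the followed
branch. If initial-condition dependence (bistability) matters for a
question, it surfaces as a difference between warm- and cold-started
solves and is visible in the records, never averaged away. Extinction
thresholds are refined by bisection (`find_extinction_effort()`,
relative tolerance 10⁻⁴, warm-started from the alive side); revenue-curve
maxima by plateau-tolerant neighbour comparison on the grid followed by
golden-section refinement on re-solved equilibria
(`analyze_revenue_curve()`). The default effort grid for scenario runs is
201 points from 0 to an adaptively doubled ceiling at which both species
are extinct; tests and examples use coarser or composite grids (40–100
points, finer below the first extinction) to keep runtimes in minutes —
the qualitative checks are grid-robust.

Degenerate corners are kept well-defined: at $\omega = 1$ the
sole-exclusive pool has $K = 0$ and simply relaxes to zero while remaining
a state variable; $E = 0$ gives zero flows and an undefined (NA) discard
ratio rather than a 0/0; a species with zero catchability in both fished
stages has an infinite extinction threshold, and a species already absent
at $E = 0$ reports NA.

## What the model run produces

Under the default parameterisation the package reproduces a consistent
qualitative picture, all of it asserted by the test suite:

* Plaice is the superior competitor: its biomass rises monotonically with
  $\omega$, sole's falls, and sole is competitively excluded at
  $\omega \approx 0.90$; unfished adult plaice biomass exceeds adult sole
  biomass.
* Without competition, harvesting depresses adult biomass monotonically
  while juvenile and large-juvenile biomass are hump-shaped
  (overcompensation through relaxed intraspecific competition), so the
  discarded fraction of the catch rises with effort. Plaice is fished out
  long before sole (E* ≈ 70 vs ≈ 1024 in the arbitrary effort unit —
  ordinal statements are the meaningful ones on this axis).
* Under strong overlap, moderate harvesting *increases* sole biomass —
  the release from plaice competition outweighs the direct mortality —
  until plaice goes extinct, after which only the direct effect remains.
* The combined revenue-effort curve is unimodal without competition, with
  the peak at an effort where both species persist and sole (ten-fold
  price) supplying most of the revenue. Under competition
  ($\omega = 0.8$) it is bimodal: a low-effort plaice-driven maximum, a
  local minimum, and a global maximum at the edge of plaice extinction
  driven by released sole. In this implementation that global maximum
  sits *at* the transcritical kink (the refined maximiser lands a few
  percent below E*, where plaice biomass is already negligible) rather
  than strictly beyond it: the coexistence branch rises up to E* and the
  sole-only branch declines from it. The management reading is the same —
  revenue maximisation pushes effort to the level that eliminates the
  less valuable, competitively superior stock — but the literal position
  of the maximiser relative to E* is a knife-edge property here.
* Re-running with a single shared set of stage boundaries for both
  species (`scenario_equal_sizes()`, default: the plaice boundaries, an
  explicit argument because the choice is genuinely open) preserves
  plaice's competitive superiority and the revenue bimodality. It does
  *not* shift both extinction thresholds to higher effort in this
  implementation: whichever species keeps its own boundaries keeps its
  threshold, and each species' own stage structure turns out to be the
  more harvest-robust one (e.g. sole's threshold drops from ≈1024 to
  ≈285 under plaice boundaries). The corresponding acceptance check is
  deliberately left failing rather than weakened.

## Synthetic observations

`generate_pseudo_observations()` emulates what a calibration of this
model against survey and market data would consume: equilibrium stage
biomasses and discard fractions on an effort grid, each multiplied by
independent lognormal noise with unit median and coefficient of variation
`noise_cv` (sdlog $= \sqrt{\ln(1+cv^2)}$; lognormal keeps the positive
quantities positive). It is deterministic for a fixed seed and leaves the
caller's RNG state untouched. It emulates *observation* noise only: no
process noise, no seasonality, no transient dynamics, no size-selectivity
error, and the "observations" come from the model itself. Passing
parameter-recovery tests therefore demonstrates that the calibration
machinery is consistent and well-conditioned (with 5% noise, the median
recovery error of the large-juvenile catchabilities over 20 seeds is
well under 15%), not that the model fits real North Sea data.

## Known limitations

Biomass, not numbers: the stage-structured approximation is exact at
equilibrium but only approximate in transients, and no cyclic or chaotic
attractors are analysed. No seasonality, space, stochastic demography, or
fleet economics (effort costs are out of scope, so "revenue", not
"profit"). The effort unit is arbitrary; only orderings and shapes along
the effort axis are interpretable. And the default large-juvenile
catchabilities are retained verbatim for fidelity to the published table
even though the package's own calibration shows them inconsistent with
the stated discard targets (see above) — users who want the targets
realized should run `tune_catchability()` and use its output.
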