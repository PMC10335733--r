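---
title: "Modelling T6SS duels: kinetics, mechanics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling T6SS duels: kinetics, mechanics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

The type VI secretion system (T6SS) is a contact-dependent weapon: a cell
builds spring-loaded sheath structures and fires them into whatever it is
touching. When two armed strains of *Vibrio fischeri* meet on a surface,
the outcome of the battle depends on quantities that are hard to
manipulate experimentally -- how fast each strain switches its weapon
system on, how fast it builds and fires sheaths, what the weaponry costs
in growth, and how long a killed cell's corpse keeps occupying space.
`t6sim` implements a two-level model of this system: a stochastic
subcellular model of T6SS kinetics, embedded in a two-dimensional
off-lattice agent-based model (ABM) of a growing monolayer, plus scenario
runners for the standard in-silico competition experiments.

## The two-stage subcellular model

Each cell (or, for analytical work, each non-growing "reactor") carries
two internal variables: an activation flag $G$ and a sheath count $N$.

**Stage 1 -- activation.** A cell starts activated with probability
$p_0$. An inactive cell waits a deterministic period $\tau_+$ (surface
sensing, protein accumulation), then switches on at a constant rate
$\lambda_+$; activation is irreversible in this model. For a large
population the activated fraction is

$$P(t) = \begin{cases} p_0 & t < \tau_+ \\
p_0 + (1 - p_0)\left(1 - e^{-(t - \tau_+)\lambda_+}\right) & t \ge \tau_+,
\end{cases}$$

implemented in `activation_probability()`. The parameters for one strain
live in a `kinetic_params()` object.

**Stage 2 -- assembly and firing.** An activated cell synthesises sheaths
at a constant rate $\lambda_s$ (sheath initiation is limited by a
low-copy structural component, so a constant rate is the natural model)
and fires each existing sheath independently at rate $\lambda_f$. The
count $N$ therefore follows an immigration--death process whose
stationary law is Poisson with mean
$\bar N_\infty = \lambda_s / \lambda_f$ (`steady_state_mean()`). Because
$\lambda_s$ and $\lambda_f$ cannot be measured separately, strains are
parameterised by $\lambda_s$ and $\bar N_\infty$, giving
$\lambda_f = \lambda_s / \bar N_\infty$.

Three computational routes into this model are provided, and they
cross-validate each other in the test suite:

* `ssa_ensemble()` -- an exact event-driven (Gillespie) simulation per
  reactor; no time-discretisation error. This is the reference.
* `step_activation()` / `step_sheath_dynamics()` -- fixed-step tau-leap
  updates, the form used inside the ABM where all cells advance on a
  common clock.
* `transient_pmf()` -- direct numerical integration of the chemical
  master equation of the joint $(G, N)$ process (via `deSolve::lsoda`,
  tolerances $10^{-10}$/$10^{-12}$), with the state space truncated at
  $n_{max} = \lceil m + 10\sqrt{m} + 10 \rceil$, $m = \lambda_s/\lambda_f$;
  the neglected tail is far below the integration tolerance, and mass
  reaching the last bin raises an error rather than being silently lost.

**Tau-leap details.** With step $\Delta t$ (the package enforces
$\text{rate} \times \Delta t \le 0.1$), the sheath update fires each
existing sheath with probability $1 - e^{-\lambda_f \Delta t}$, then adds
at most one sheath with probability exactly $\lambda_s \Delta t$, and a
sheath born within the step is exposed to half a step of firing. The
half-exposure (midpoint) rule matters: a naive "synthesise with
probability $1 - e^{-\lambda_s \Delta t}$, then fire" scheme biases the
stationary mean downward by $O(\lambda \Delta t)$ -- about 4% at the step
the ABM uses -- whereas the midpoint scheme's relative bias is
$(\lambda_f \Delta t)^2/12 \approx 5\times10^{-5}$. The reaction step
defaults to $\min(0.005, 0.1/\max \text{rate})$ hours.

## Fitting and count statistics

`fit_activation_curve()` reproduces the estimation protocol used for
surface-activation assays: $p_0$ is the mean of the two earliest
observations (the curve is flat during the waiting period), and
$(\tau_+, \lambda_+)$ minimise the residual sum of squares of $P(t)$ over
all points. The objective has kinks where $\tau_+$ crosses an observation
time, so the optimiser is multi-started from a $20 \times 20$ grid over
$\tau_+ \in [0, \max t]$, $\lambda_+ \in [0, 5]\,\mathrm{h}^{-1}$, the
best three starts are refined with bounded quasi-Newton steps, and a
derivative-free polish guards against stalling on a kink. On noiseless
forward data the truth is recovered to $10^{-4}$; under binomial counting
noise at the census sizes of real assays (~680 cells per time point) the
activation rate is recovered within ~20%.

`poisson_gof_test()` compares a sheath-count histogram with the Poisson
law sharing its mean: expected counts with the upper tail lumped,
adjacent bins pooled until every expected count is at least 5, and
degrees of freedom equal to pooled bins minus two (total and estimated
mean). `two_sample_chi2()` is the matching contingency test for two
histograms. The pooling threshold and df correction are standard
(Cochran's rule); they are stated here because different choices move
p-values near the boundary. `fit_exponential_decay()` fits
$a e^{-bt}$ on the log scale for target-census decay curves, excluding
points before 2 h by default, where census changes reflect the
liquid-to-surface transition rather than killing.

## The agent-based model

Cells are spherocylinders of fixed radius (default 0.5 µm) growing in a
monolayer on a viscous substrate; all lengths are in micrometres, all
times in hours.

* **Growth and division.** Elongation is exponential in total length at
  the strain's growth rate; a cell divides after *adding* a fixed length
  `delta_L` since birth (the adder rule; default 2 µm, the newborn
  length, so division is roughly a doubling). Daughters lie end-to-end
  across the mother's extent, inherit her activation state, split her
  sheaths as Binomial(N, 1/2), and receive independent angular noise
  (SD 0.05 rad) so colonies buckle rather than forming perfect lines.
* **Mechanics.** Overlapping surfaces repel with a Hookean force
  $k_e \delta$ applied at the closest axis points; translation is damped
  by $\zeta L$ and rotation by $(\zeta/12) L^3$ (the slender-rod ratio).
  Defaults $k_e = 20$, $\zeta = 1$ give a relaxation time
  $\zeta/k_e = 0.05$ h, much shorter than a doubling time, and the
  explicit sub-step sits at the stability bound
  $0.1\,\zeta/k_e = 0.005$ h. A displacement exceeding half a radius in
  one sub-step aborts the run as numerically unstable. Cells with exactly
  coincident axes (a measure-zero degeneracy) use a deterministic
  fallback direction perpendicular to the lower-indexed cell's axis.
* **Growth restriction.** Elongation is attenuated by
  $\max(0, 1 - \sum\delta/p^*) \times \max(0, 1 - \phi_{occ}/K)$ where
  $\sum\delta$ is the cell's summed contact overlap ($p^* = 1$ µm
  arrests growth), $\phi_{occ}$ the occupied-area fraction and $K$ the
  carrying capacity (default 0.8, near the packing limit of a rod
  monolayer).
* **Combat.** Two cells are "in contact" when their surface gap is at
  most `contact_eps` (0.25 µm). Each shot picks uniformly among
  $\max(k, k_{max})$ slots, where $k$ is the number of contacts: the
  $k$ contact slots hit that neighbour, the rest are misses into the
  medium. $k_{max} = 6$ (the coordination number of rods in a monolayer)
  reproduces the observation that isolated cells waste shots while
  surrounded cells rarely miss; $k_{max} = \infty$ recovers
  "always hit a contact if one exists". A hit on a clonemate does
  nothing; a single hit kills a non-clonal live cell, which then lyses:
  it stops growing and firing but keeps its geometry -- shielding its
  killer's later shots -- for `tau_lys` hours (default 0.5 h) before
  disintegrating. Cost couples weapons to physiology: an *activated*
  cell grows at $r_0' = \max(0, r_0 - c\lambda_s)$; inactive cells are
  not yet producing sheaths and grow at $r_0$.

Each reaction step executes: contact-graph build, mechanics relaxation
(reusing the just-built pair geometry; this is the trailing mechanics
pass of the conceptual cycle rotated to the front, a pure relabelling of
step boundaries whose effects are second order in $\Delta t$), then
activation, sheath synthesis/firing, firing resolution, lysis countdown
and removal, attenuated growth, and division. All randomness comes from
R's RNG, so `set.seed()` makes whole competitions bit-identical; each
replicate of a scenario gets an independent seed drawn under the master
seed and recorded in the output metadata.

## Strains and scenarios

`strain_es401()` and `strain_fqa002()` encode the two natural
light-organ isolates: ES401 activates faster ($p_0 = 10\%$,
$\lambda_+ = 0.6\,\mathrm{h}^{-1}$) than FQ-A002 ($5\%$,
$0.25\,\mathrm{h}^{-1}$), both with $\tau_+ = 1$ h,
$\lambda_s = 21\,\mathrm{h}^{-1}$, $\bar N_\infty = 3.5$ (so
$\lambda_f = 6\,\mathrm{h}^{-1}$), $\tau_{lys} = 0.5$ h. The activation
rates are the fitted assay values scaled five-fold (the assays were done
in sealed, oxygen-limited imaging chambers; scaling preserves the
between-strain ratio, which is what drives the outcome). The `vasA`
mutants cannot fire ($\lambda_f = 0$) but still pay the expression cost.

Growth parameters are not measurable from the published assays, so the
package fixes $r_0 = 1\,\mathrm{h}^{-1}$ and $c = 0.3/21$, giving both
wildtype strains $r_0' = 0.7\,\mathrm{h}^{-1}$ (doubling every hour, a
typical *Vibrio* surface rate); the strains' growth rates are set equal
because the biological strains kill and grow at comparable rates once
activated.

**Seeding density.** Coincubation assays spot 5 µl of an OD$_{600}$ = 1.0
1:1 mixture -- roughly 0.4 cells/µm², i.e. a near-confluent lawn -- so
the two strains are interleaved and touching from the start. The default
seeding therefore fills 30% of the arena (`seed_occupancy = 0.3`, about
as dense as random sequential placement of rods can reliably go), with
well-mixed random strain assignment. This matters mechanistically: with
sparse seeding each founder grows into a clonal microcolony and
inter-strain contact only begins after the slow activator has caught up,
which erases the early-activation advantage and (contrary to both the
wet and published in-silico experiments) yields near-coexistence in the
unprimed duel. Unprimed cells start with their strain's $p_0$ activated;
primed cells all start activated. Activated cells at seeding carry
steady-state Poisson($\lambda_s/\lambda_f$) sheath loads -- primed cells
come from a 6 h surface incubation, long past the $1/\lambda_f$
relaxation time -- and inactive cells carry none.

Scenario runners: `run_competition()` (confined periodic duels, the
colony-interior setup), `run_target_elimination()` (one armed vs one
unarmed strain), `run_range_expansion()` (open arena, circular inoculum;
unarmed survivors persist only in microcolonies at the expanding edge),
and `phase_sweep()` (fully primed resident at
$\lambda_{s,res} = 20\,\mathrm{h}^{-1}$ against competitors at
$\lambda_{s,comp} = \lambda_{s,res}\beta/(1-\beta)$ with shared
normalised cost $\hat c = c\,\lambda_{s,res}/r_0$). The sweep is the one
scenario run from *sparse* seeding (2% occupancy in the shipped tests):
its axis of interest is the growth-versus-weaponry tradeoff, which needs
growth headroom to express itself — seeded near-confluent, the arena
saturates after ~2.4-fold growth and a cheap fast-growing competitor can
no longer outgrow an expensive resident, muting the high-cost corner of
the phase diagram. Sparse seeding also matches the regime in which the
high-cost, matched-arsenal corner coexists precisely because colonies
barely grow enough to establish contact. Outcomes are
summarised by window area fractions (measured in a centred window to
avoid edge effects; fractions are of total live cell area) and by
$\phi = (N_{res} - N_{comp})/(N_{res} + N_{comp})$ on live counts --
lysing cells are corpses and are excluded.

## What the synthetic generators do and do not emulate

`make_activation_series()` draws binomial counting noise around the
closed-form activation curve -- the noise structure of counting sheathed
cells in microscopy fields -- and `make_sheath_histogram()` tabulates
exact-SSA reactor ensembles. They deliberately do **not** emulate:
cell-cycle coupling of sheath numbers (division halves $N$ in real
growing cells, which is why reactor ensembles run hotter than real 2 h
censuses), field-of-view clustering, segmentation errors, or
strain-specific deviations from Poisson sheath statistics that real 2 h
populations show. Passing tests on these fixtures therefore validates
the inference machinery, not the biological completeness of the model.

## Numerical and scale choices in the shipped tests

The test suite runs the full pipeline at sizes chosen for a single CPU:
duels on a 150 µm periodic arena with 10 replicates for 24 h
(roughly 2,400 seeded and 7,000 final cells per replicate, ~20 s each);
the phase sweep on a 3 × 3 $(\beta, \hat c)$ grid at 80 µm with 10
replicates per point for 10 h; property checks (clonemate immunity over
more than $10^6$ shots, symmetry nulls, oracle comparisons) at 25--100 µm.
At these sizes the faster activator takes ~85% of the central window in
unprimed duels (published full-scale simulations: 91.4% ± 1.8% at
388 µm over 100 replicates -- smaller domains leave relatively more
boundary between strain sectors), primed duels sit near 50%, and unarmed
duels remain at the seeded ratio. The `scripts/acceptance.R` entry point
recomputes the two analytic/ensemble reference quantities (the
steady-state ensemble mean and the 1 h activated percentage) from
scratch at full precision.

## Known limitations

Strictly 2D monolayers (no second layer, no 3D buckling); no T6SS
deactivation or firing-independent sheath decay; no retaliatory
("tit-for-tat") aiming, no multi-hit death thresholds, no reuse of fired
components, no contact-independent toxicity; mechanical constants are
plausible rather than fitted (exposed in `mechanics_params()`); and the
slot-based miss model is a stand-in for whatever angular geometry real
firing has -- only its single free parameter $k_{max}$ is exposed.
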