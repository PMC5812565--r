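---
title: "Modelling receptor diffusion in crowded postsynaptic membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling receptor diffusion in crowded postsynaptic membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowddiff)
```

## The problem

AMPA-type glutamate receptors diffuse laterally in the postsynaptic membrane,
and their retention at the postsynaptic density (PSD) is shaped by three kinds
of crowding: immobile transmembrane proteins that sterically reflect a
receptor, submembranous scaffold proteins that partially reflect *and*
transiently bind it, and the receptor population itself, whose members exclude
one another. `crowddiff` simulates all three on two complementary
representations and quantifies their effect on mobility through the
ensemble-averaged mean squared displacement (MSD).

## The lattice model

Space is a periodic square lattice of `n_side` sites. A tracer performs one
hop attempt per time step $\Delta t$, drawing one of four directions with
equal probability (the quartile rule on a single uniform variate). The hop
length is fixed by requiring that free hopping reproduce two-dimensional
normal diffusion, $\langle r^2\rangle = 4D t$, giving
$\Delta l = \sqrt{4 D \Delta t}$. With the receptor constants — free
diffusion coefficient $D = 0.2\times10^{-3}\,\mu m^2\,ms^{-1}$ measured in
the extrasynaptic membrane and $\Delta t = 10^{-3}$ ms — this yields
$\Delta l \approx 8.9\times10^{-4}\,\mu m$, and a lattice of $1119^2$ sites
spans very nearly $1\,\mu m^2$:

```{r constants}
dl <- derive_step_length(0.2e-3, 1e-3)
c(step_length_um = dl, n_side = derive_n_side(1, dl))
```

Obstacles occupy single sites and never move:

* **CRO** (completely-reflecting obstacle): a hop into it is always refused.
* **PRO** (partially-reflecting, binding obstacle): a hop into it is refused
  with probability $P_{reflect}$ (0.5 throughout); a tracer that does enter
  is *bound*, and escapes at each later step with the Boltzmann probability
  $P_{escape} = e^{-E/k_BT}$. The study grid uses $E = 2, 6, 10\,k_BT$
  (weak, intermediate, strong). A bound tracer that passes its escape draw
  immediately attempts one isotropic hop; if that hop is refused it remains
  on the scaffold site and stays bound, so "bound" and "occupies a PRO site"
  are the same predicate.

A note on the escape inequality: taken literally, the prose rule "unbind when
the variate is at least $P_{escape}$" would make strong binding release
almost surely, inverting the meaning of the Boltzmann factor and every
downstream result. The engine therefore unbinds when the variate is *below*
$P_{escape}$; the literal reading is retained behind
`escape_rule = "literal"` for comparison.

## Self-crowding and the two-pass sweep

With steric exclusion between tracers, at most one tracer occupies a site and
a hop into an occupied site is refused; a PRO holding a bound tracer behaves
as a CRO. Updating tracers one by one then creates an artifact: a tracer may
be refused because its target is occupied by a neighbour that vacates the
site *later in the same time step* — false self-blocking, an artifact of
update order, not of the physics being modelled. The engine removes it the
way the model prescribes:

1. pre-draw every tracer's direction (bound tracers first pass the escape
   check);
2. sweep sequentially, applying the obstacle/occupancy rules; tracers
   refused because of another *tracer* are labelled;
3. re-examine the labelled set once, in order, against their originally
   chosen destinations: those now free hop (a freed PRO destination gets a
   fresh reflection draw); the rest stay;
4. advance time.

Exactly one re-examination pass is performed, matching the scheme's
definition; a chain A←B←C may therefore resolve only partially within one
step. Sweep order is fixed index order — the second pass is itself the remedy
for order artifacts, and the canonical two-tracer configuration resolves
identically under both orders:

```{r figline}
cfg <- lattice_config(n_side = 10)
f <- build_obstacle_field(cfg)
step_population(cfg, f, row = c(5, 5), col = c(5, 6),
                directions = c("right", "right"), recursive = TRUE)$moved
step_population(cfg, f, row = c(5, 5), col = c(5, 6),
                directions = c("right", "right"), recursive = FALSE)$moved
```

MSD is always computed from *unwrapped* displacement accumulators; wrapped
coordinates on a periodic box would make squared displacement meaningless
once a tracer crosses the boundary.

## The continuous-space reference

The hard-disk engine is an independent check on the lattice algorithm's
treatment of self-crowding. Receptors are disks of exclusion radius 6 nm in a
periodic box; each step every disk sequentially proposes a Gaussian
displacement with per-axis standard deviation $\sqrt{2 D \Delta t}$ and the
proposal is rejected if any pair of centres would come closer than twice the
radius (minimum-image). Rejection of overlapping proposals is the standard
Monte-Carlo realization of hard-core exclusion; deterministic specular
reflection is not provided. A cell grid accelerates the pair checks without
changing any outcome. Initial placement is uniform rejection sampling; above
the saturation of that process (area fraction ≈ 0.5) a square-grid seed plus
an unrecorded equilibration run is used and recorded in the manifest.

## Analysis

From trajectories the package computes the ensemble MSD (average over tracers
of squared displacement from the measurement origin, then an unweighted mean
over replicate simulations — no time-averaging over sliding origins anywhere),
and characterizes it through the power law
$\langle r^2\rangle = 4 D t^\alpha$, linear in the log-log representation
$\log(\langle r^2\rangle/t) = \log 4D + (\alpha - 1)\log t$ (natural
logarithms). `fit_alpha()` classifies profiles the way obstructed-diffusion
studies read them:

* flat global slope (magnitude ≤ 0.05 by default) → **normal**, $\alpha = 1$;
* steeply declining late-time window (final 25% of the log-time span, slope
  ≤ −0.5 and locally linear) → **anomalous**, with $\alpha$ and $D$ from the
  tail fit;
* otherwise → **transition**, with $\alpha$ fitted on the initial segment up
  to the crossover, detected as the first time after which local slopes
  (sliding windows of one fifth of the log-time span) stay flat; the
  crossover time and the MSD traversed by then (crossover length) are
  reported.

These windows and tolerances are package decisions — the source analyses
name the quantities but give no estimator — and all are exposed as arguments.
Fitted $\alpha$ is clipped to $[0, 1.05]$ and values within the flatness
tolerance of 1 report as exactly 1; the unclipped global-slope estimate is
kept as `alpha_raw` for diagnostics. Time-dependent mobility follows
$D_{app}(t) = D\,t^{\alpha-1}$ and $D_{inst}(t) = \alpha D\,t^{\alpha-1}$.
(The apparent-diffusion exponent is sometimes typeset with the sign flipped;
the form used here is the one under which $4 D_{app}(t) t$ reproduces the
MSD and $D_{app}$ decays with time for subdiffusion, which is how the
quantity is described and used.) The **effective** coefficient $D_{eff}$ is
$D_{app}$ evaluated at the 2 s observation horizon — for normal diffusion
simply the fitted $D$:

```{r deff}
t <- exp(seq(0, log(2000), length.out = 50))
fit <- fit_alpha(data.frame(time_ms = t, msd_um2 = 4 * 2e-4 * t))
c(alpha = fit$alpha, D_eff_nm2_us = fit$D_eff_nm2_us)
```

`fit_msd_powerlaw()` fits the same model to arbitrary two-column MSD tables
(for example externally digitized single-particle-tracking curves), by
log-log regression by default or nonlinear least squares on request.

## Geometry bridge

`molecular_footprint()`, `area_fraction_from_density()` and
`density_from_count()` convert molecular dimensions and areal densities into
the dimensionless area fractions the engines consume: a 16 × 8 nm receptor
footprint is 128 nm², so 3–5 receptors per $\mu m^2$ of extrasynaptic
membrane occupy a fraction 0.00038–0.00064, synaptic densities of
650–3000 $\mu m^{-2}$ occupy 0.08–0.4, and PSD-95 scaffold discs of radius
2.5 nm at 3000 $\mu m^{-2}$ occupy 0.059. The chain reproduces the printed
values from the printed inputs; note the densities themselves are already
rounded upstream. Internally every area is carried in $\mu m^2$ with explicit
conversion from nm².

## Problem sizes, reproducibility and what the tests show

The full study conditions ($1119^2$ sites, 2 s measurements, hundreds of
ensembles per condition) are supported but deliberate overkill for routine
use; the package's desk presets — a $200^2$ lattice, 200 ms measurements
($2\times10^5$ steps), and tens of replicates — keep every sweep cell in the
seconds-to-minutes range while holding $\Delta l$, $\Delta t$, $D$ and all
probabilities at their physical values, so area fractions remain the
controlled variables. Every stochastic element is driven by R's RNG; engines
accept a seed, and sweeps derive one independent stream per
(cell, ensemble) pair via `derive_seed()`, making any row regenerable from
its manifest entry alone. Binding conditions are annealed for 2 s before
measurement; a monitor can record the bound fraction during annealing, which
settles at the mean-field kinetic balance
$f_b = a(1-P_r)\,/\,[a(1-P_r) + P_{esc}(1-a)]$ — close to, but not exactly,
the Boltzmann occupancy, because entry passes a reflection draw and
scaffold-to-scaffold hops keep a tracer bound.

Two empirical notes, measured with this package and worth stating plainly.
First, with the algorithm implemented exactly as specified, self-crowding at
tracer fractions up to ~0.01 yields *normal* long-time diffusion with a
mildly reduced coefficient — the behaviour established for tagged particles
in two-dimensional exclusion processes — rather than a strong anomaly; claims
of near-complete confinement at such dilute self-crowding are not reproduced
by these rules. Second, in the lattice-versus-hard-disk comparison
(normalizing MSD by the free $4Dt$), the two-pass and single-pass variants
are indistinguishable at very low density, differ clearly at moderate and
high density, but the site-fraction to disk-area-fraction correspondence is
not quantitative enough to make the two-pass variant systematically the
closer one at every density. The synthetic worlds also idealize real
membranes — obstacles are immobile points, binding energies homogeneous,
the geometry square and closed — so green tests demonstrate correctness of
the algorithms and analysis, not biological completeness.

## Known limitations

No rotational diffusion, no exchange with an extrasynaptic reservoir, no
mobile obstacles, no heterogeneous binding energies, and no percolation
analysis (the square-lattice threshold near 0.4–0.5 is context, not a
computed quantity). The continuous engine is obstacle-free by design: it
exists to check self-crowding, not to re-implement the obstacle taxonomy in
continuous space.
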