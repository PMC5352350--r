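---
title: "Methods: a hybrid multiscale model of myeloma in the marrow niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid multiscale model of myeloma in the marrow niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`habm` simulates the growth of multiple myeloma inside a 3D bone-marrow
microenvironment across three coupled scales.

**Intracellular scale.** Two Hill-kinetics ODE systems run inside the
agents. Every interaction is a saturating production term
$k\,x/(H+x)$ and every species carries one first-order decay $-d\,x$;
states are expressed in fold-change units relative to their level at
$t=0$ (all species start at 1, mirroring the RPPA normalisation of
phospho-protein panels).

* The *BMSC stiffening system* (7 states) transduces the local SDF-1
  level through PI3K/MEK, FAK, RhoA/ERK and MYL2 into a dimensionless
  `stiffness` state. The state is referenced to the time-matched
  zero-dose trajectory and mapped to Pascals by an affine, clamped map
  anchored at two experimental observations: the resting myeloma BMSC at
  400 Pa and the saturating 60-min SDF-1 response at 530 Pa. The
  relative-dose scale sets 1.0 at the saturating reference; the shipped
  constant `sdf1_rel_per_nM` places molar doses on that scale and is
  calibrated so that 5 nM SDF-1 yields 526 Pa.
* The *MIC adhesion/survival system* (9 states) transduces niche
  stiffness (normalised by the 530 Pa ceiling) through FAK, Rac/PI3K,
  AKT, JNK/cJUN and NF-kB into two probability readouts, `Adhesion` and
  `Survival`. Survival additionally carries a subtractive
  bortezomib-inhibition term $-K\,D/(H_D+D)$. Readouts are clamped to
  $[0,1]$ because they are consumed as probabilities. Total adhesion adds
  a constant 20-percentage-point non-stiffness contribution to the
  ODE-driven component.

**Intercellular scale.** Five agent compartments live on a cubic lattice
(one cell diameter per site) with an inscribed cylindrical mask: static
BMSC scaffold cells on every 4th site, and mobile MIC, MM, CD8+ CTL and
Treg agents at one per site. Each 2-h step every agent computes behavior
probabilities from its local environment (embedded ODE readouts or Hill
couplings) and commits decisions by die casting. MICs climb the local
stiffness gradient, attach to BMSCs (attachment shields them from CTL
lysis by a 0.3 protection factor), and on cycling either self-renew into
two MICs or differentiate into two MMs, with the self-renewal
probability a Hill function of local stiffness. MMs random-walk,
proliferate and die, with a hard passage limit (LGN = 5) after which a
lineage dies. CD8 cells chemotax toward the nearest myeloma cell within
a 5-site radius and lyse adjacent tumor cells; their proliferation is
suppressed by TGF-beta and adjacent Tregs and boosted by lenalidomide.
Tregs follow CD8 cells, expand with TGF-beta, and suppress adjacent CD8s
by a dice-rolled choice between one-cycle arrest and apoptosis.

**Tissue scale.** SDF-1 (secreted by MICs) and TGF-beta (secreted by MMs
and BMSCs) diffuse by an explicit 7-point-stencil scheme with Dirichlet
boundary (default 0, a sink-like marrow edge). Drugs are spatially
uniform and follow a half-open 144-h treatment window. Bortezomib kills
MICs through the survival ODE and MMs through a Hill kill term;
lenalidomide boosts CD8 and suppresses Treg proliferation; thalidomide
attenuates the effective SDF-1 input of the BMSC system and BMSC
TGF-beta secretion.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| lattice | 50x50x50, cylindrical mask | sites | reference domain; one cell diameter per site |
| step | 2 | h | population counting interval; ODEs run to quasi-steady readouts within a step |
| horizon | 600 (672 for the 4-week growth experiment) | h | study horizon |
| initial counts | 100 MIC / 100 MM / 20 CD8 / 5 Treg | cells | seeding of a nascent lesion, mixed in a central sphere |
| D (both cytokines) | 2 | sites^2/h | 3D RMS displacement of about 5 sites per 2-h step |
| treatment window | 144 | h | acute 6-day regimen |
| LGN | 5 | passages | MM lineage exhaustion limit |
| cycle length | 24 (tumor), 12 (activated lymphocytes) | h | sets the minimum division interval |
| sensing radius | 5 | sites | CTL/Treg chemotaxis range |
| max doses | BTZ 5 nM, LEN 10 uM, Thal 10 uM | - | level-10 anchors of the 11-level dose grids |

The remaining behavior constants (per-step probability ceilings and Hill
constants of each coupling) are calibration knobs; their shipped values
are fitted so the assembled model reproduces the population-level
anchors (see below) and live in `inst/extdata/abm_rules.json`.

## Calibration

The ODE parameters are estimated by a real-coded genetic algorithm
(tournament selection, blend crossover, gaussian mutation on log scale,
elitism, optional Nelder-Mead polish) minimising the L1 distance between
model trajectories and observation tables, with log-uniform bounds
$k,d \in [10^{-3}, 10^2]$, $H \in [10^{-2}, 10]$ spanning the normalised
data scale.

Because the quantitative proteomics tables behind the published panels
are not redistributable, the package ships a synthetic-proteomics
generator that emulates their structure: trajectories of the generating
("true") kinetics sampled on the assay grids (BMSC panel at 0/5/10/15/60
min; MIC panel at 0/0.5/1 h with adhesion/survival readouts at 24/96 h),
multiplied by lognormal noise (CV 0.1), with the $t=0$ entries fixed at
1. Calibration uses several conditions jointly, mirroring the assay
designs: three SDF-1 dose levels for the BMSC system, and for the MIC
system the two seeding stiffnesses (100 and 400 Pa) plus drug-treated
survival under 5 nM bortezomib. Multi-condition data are essential: a
single condition only constrains each input edge through the product
$k\,u/(H+u)$ at one input level $u$, leaving the dose response
unidentified.

Two non-identifiabilities remain and are handled explicitly:

* *Output scale.* The absolute magnitude of the stiffness response is
  absorbed by the affine Pa map, which is re-anchored after every fit;
  only the dose-response shape matters, and the fit is validated against
  the generating shape on a dose grid.
* *Output-node gains.* The adhesion/survival gains (`k10`, `k11`) and
  the bortezomib inhibition strength are re-anchored exactly to the
  population assays after the GA fit: 47% stiffness-driven adhesion at
  400 Pa, 90% drug-free survival at day 6, and an 89.2% viability
  reduction under 5 nM bortezomib.

Agent-behavior constants are tuned against the population-level growth
and treatment observations (5.98-fold MIC expansion in 4 drug-free,
immune-free weeks; 49.5% myeloma reduction after 2 days of 1.5 nM
bortezomib; 38.4%/46.4% CD8+ expansion under 5/10 uM lenalidomide),
replicating the practice of fitting rule parameters against training
data over repeated stochastic runs.

## Numerical choices

* ODE integration: `deSolve::lsoda` (the same stiff-capable solver
  family used for such signaling systems), rtol 1e-6 / atol 1e-9.
  Hill arguments are floored at 0 inside the right-hand side; only
  `Survival` can transiently cross zero (its drug term is subtractive),
  and returned trajectories are clamped at 0.
* Diffusion: forward-Euler 7-point stencil, sub-stepped at the stability
  bound $D\,\Delta t \le 1/6$ (unit spacing). The kernel is shared
  between the user-facing `diffuse()` and the compiled simulation
  engine and is tested against a dense-Laplacian matrix oracle.
* Scale coupling: fields are frozen within each 2-h step; BMSC stiffness
  is the 60-min ODE response to the local SDF-1 read at step start, and
  the per-step MIC death probability spreads the day-6 survival ratio
  uniformly over the 72 steps of the 144-h exposure. The engine
  evaluates these through dense interpolation tables built from the ODE
  layer at run start (the ODEs relax in minutes, two orders of magnitude
  below the step).
* Stochastic engine: the per-step agent phase runs in compiled code for
  speed, drawing from R's RNG so a single `set.seed` makes whole runs
  bit-reproducible. Agents act in a freshly shuffled order each step
  (removing grid-scan bias); division placement and movement ties break
  uniformly at random. The R-level rule primitives (`decide`,
  `hill_prob`, `mic_fate`, `divide_site`, `migrate_step`,
  `attempt_lysis`, `treg_suppress`, ...) implement the same formulas and
  carry the statistical unit tests.
* Replicates: paired seeding — replicate *i* of any two configurations
  under the same master seed shares its RNG seed — acts as
  common-random-number variance reduction for treatment contrasts.

## Design decisions

* The marrow is a rectangular lattice with an inscribed cylindrical mask
  (agents only inside the cylinder), honoring both the cylindrical organ
  geometry and the rectangular grid.
* BMSCs are a static reticular scaffold: no migration or proliferation;
  scaffold sites are not free for mobile agents.
* Adjacency, division placement and movement use the 3D Moore
  neighborhood (26 sites), the densest local coupling on a cubic
  lattice.
* A division committed without free space is deferred: the cell stays in
  M-phase and re-attempts as space appears.
* The lineage is the simplified two-stage MIC to MM process; a
  differentiation event consumes the MIC and yields two MM daughters.
* Whether lysis protection applies is decided by the target's attachment
  state at the moment of attack.
* The 5.98-fold growth experiment extends the horizon to 672 h (4
  weeks); drug experiments use the 600-h horizon.
* Evaluation time for survival ratios in the dose sweeps is the end of
  the 144-h treatment window.
* Synergy classification uses a +/-0.02 band around 1 for "additive";
  a fully lethal triple combination (zero surviving myeloma) returns a
  maximal-synergy sentinel rather than a number.

## Problem sizes

Desk-scale defaults keep every bundled experiment single-CPU friendly:
50 replicates for the growth and bortezomib contrasts, 150-350 for the
lenalidomide contrasts (the CD8 compartment starts from 20 cells, so its
relative branching noise is the largest of the four compartments; the
contrasts run on the 144-h window, are damped by paired seeding, and use
the larger replicate counts their noise demands), 5000 samples for the
uncertainty experiments, and a reduced dose grid (e.g. 3-4 levels per
drug, 3-20 replicates) for sweep demonstrations. The full factorial
(11^3 conditions x 200 replicates = 266,200 runs) is expressible with
`synergy_sweep(grid = dose_grid(), replicates = 200)` but is a
cluster-scale computation.

## What the synthetic data do and do not show

The generator reproduces the *structure* of the calibration data
(normalisation, grids, noise character, multi-condition design), not the
measured kinetics of any particular cell line; the shipped parameters
are therefore a self-consistent calibration against the published
summary anchors rather than a refit of the original tables. Passing
tests demonstrate that the machinery recovers generating dynamics from
such data and that the assembled model reproduces the anchor
observations — they do not validate the kinetics against new wet-lab
measurements.

## Known limitations

* No explicit cell mechanics, continuous-space motion, or oxygen
  gradients; drugs have no pharmacokinetics or spatial structure.
* The immune compartment is two cell types with phenomenological rules;
  no antigen specificity, exhaustion, or innate compartments.
* Cytokine fields share one diffusion coefficient and Dirichlet
  boundary; no ECM anisotropy.
* The ODE parameterisation is non-identifiable beyond its anchored
  scales; fitted parameter values are not individually interpretable
  (output-trajectory equivalence, not parameter equality, is the
  recovery contract).
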