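---
title: "Generating and simulating chemical reaction networks with crnkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and simulating chemical reaction networks with crnkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnkit)
```

## The problem

Predicting the outcome of a reactive chemical process -- pyrolysis is the
motivating example -- requires two things: a chemical reaction network (CRN)
enumerating the species and elementary reactions that matter, and a kinetic
model of that network under the experimental conditions of interest, which
are rarely constant.  crnkit implements both halves as a single workflow:
stochastic graph-move sampling generates candidate elementary reactions from
molecular connectivity alone; exploration strategies assemble those samples
into deduplicated networks; and a mass-action reaction rate equation (RRE)
integrator simulates the result under fixed or time-varying conditions, over
time scales long enough that floating-point time accumulation itself becomes
a design constraint.

## Bond perception and species identity

A molecular state is a binary connectivity matrix (CM) over atoms: entry
$(i,j)$ is 1 exactly when the interatomic distance is below
$\alpha\,(R_i + R_j)$, with $R$ a covalent radius and $\alpha = 1.1$ giving
slack for strained environments.  Bond *orders* are deliberately absent --
reactivity is modelled at the connectivity level, which keeps move
application and isomorphism checks exact and cheap.  The shipped radii table
is a standard single-bond set (H fixed at 0.37 Å so that H$_2$ at 0.74 Å is
perceived as bonded); users can override any entry, and networks explored
under different tables can legitimately differ, so the table travels with
the results.

Species identity is a canonical, hydrogen-folded SMILES string computed
from the labelled graph: hydrogens bonded to one heavy atom fold into an
H count, the remaining skeleton is canonically ordered (BLISS canonical
permutation with vertices coloured by element and H count), and a
deterministic depth-first emission with ring-closure digits produces the
string.  Radical centres are implied by valence deficit and rendered as
bracket atoms (`[CH3]`, `[CH2]`, `[H]`).  Two fragments receive the same
identity exactly when they are isomorphic as element-labelled graphs, a
property the test suite verifies against brute-force permutation search.
Charges, aromaticity and stereochemistry are out of scope.

## Graph moves and mechanism sampling

Chemical reactivity enters through a library of *graph moves*: templated
bond edits over two or three abstract atom slots with per-slot element
whitelists and relative selection weights.  The default library covers bond
formation, homolytic cleavage, atom transfer and concerted exchange.  (The
two shipped 3-slot templates generate the same application class up to slot
relabelling; both are kept so each can be weighted and named separately in
library files.)  Arbitrary libraries can be defined in a YAML move file.

One sampling step draws a move by weight, enumerates all valid slot
assignments (valence limits, forbidden-pattern screening by VF2 subgraph
isomorphism, and the bimolecular cap), applies one uniformly at random, and
then *realises* the new CM in three dimensions with the graph restraining
potential (GRP).  If any check fails, or the embedded geometry re-perceives
to a different CM, the state is restored and the move resampled; after 100
consecutive rejections (configurable) the mechanism truncates.  Rejections
never consume mechanism length.

### The graph restraining potential

The GRP is the one place where the package had genuine design freedom, since
only the decomposition into an atomic constraining term plus a molecular
separation term is fixed by the method.  The implemented form is a sum of
flat-bottom harmonic wells keyed to the bond-perception cutoffs $c_{ij}$:

* bonded pairs pay $\tfrac12 k_b (d - 0.9\,c_{ij})^2$ beyond 90 % of the
  cutoff, plus an inner wall below $0.4\,c_{ij}$ so fragments cannot collapse
  onto coincident coordinates;
* non-bonded pairs pay $\tfrac12 k_r (1.1\,c_{ij} - d)^2$ inside 110 % of the
  cutoff;
* molecule centroids closer than 4 Å pay a harmonic penalty, keeping
  separate molecules apart so no spurious inter-molecular bonds appear.

The margins mirror the $\pm 10\%$ perception slack; the energy is zero
exactly when the geometry realises the target CM with that slack.  The
gradient is analytic (finite-difference checked to $10^{-6}$), and
minimisation uses L-BFGS-B with a deterministic symmetry-breaking jitter, so
the whole embedding is reproducible without any RNG.  Newly separated
fragments are first displaced along the former bond axis by 1.5 cutoffs,
which reliably lands homolysis products in separate basins.  A pluggable
refiner hook runs after GRP minimisation and is re-checked against the
target CM -- it is the attachment point for an external electronic-structure
optimiser, and tests exercise it with identity and adversarial refiners.
Note the GRP produces *topologically correct* geometries, not
thermochemically meaningful ones.

## Network exploration

**Direct exploration** repeatedly samples mechanisms of length `radius`
from the initial system (several independent runs per iteration, each with a
seed derived from the base seed so results replay exactly) and adds every
extracted reaction and its reverse to the network.  Convergence is declared
after `rxn_convergence_threshold` consecutive iterations add nothing new,
i.e. after `threshold x parallel_runs x radius` reactions sampled without
change -- the package reports this counter so convergence claims are
auditable.

**Iterative exploration** grows the network level by level along kinetically
viable paths.  Each level samples radius-1 reactions around the current seed
species (every seed alone and every unordered seed pair, including
self-pairs), filters the cumulative network, runs a kinetic simulation
under the target conditions, and selects as next seeds every species whose
maximum concentration exceeds `seed_conc` (strict inequality, so ties at
the cutoff are excluded -- a documented, testable boundary).  Seeds may
drop out and later re-enter when new chemistry re-forms them.  Exploration
converges when the seed system is unchanged for two consecutive levels (the
default; raising it buys confidence at linear cost), and an *empty* seed
system stops the run with an explicit under-exploration warning rather than
silently returning a truncated network.  Per-level simulations always use
the discrete rate-update formalism described below.  The reaction filter
(default: no species with more than four carbons) removes every reaction
touching a disallowed species from the simulated copy -- a species that
cannot be produced cannot be consumed either -- while retaining the removed
reactions in provenance so a later, looser cap needs no resampling.

On enumerable chemistries the two explorers and a brute-force
breadth-first closure over the move space provably agree; that three-way
equivalence is an acceptance-level test.

## Mass-action kinetics under variable conditions

`build_rre()` turns a network into
$\dot c_s = \sum_i (\nu^+_{is} - \nu^-_{is})\, k_i \prod_j c_j^{\nu^-_{ij}}$
with the exact analytic Jacobian assembled from the stoichiometric
couplings.  The Jacobian is handed to the integrator as a dense matrix:
at the network sizes this package targets (tens to a few hundred reactions)
dense linear algebra inside a BDF multistep method is faster and simpler
than sparse bookkeeping, and nothing in the interface precludes swapping
the backend later.  The default integrator is deSolve's `lsode` (BDF-family
implicit multistep) with user-supplied Jacobian; the solver is selectable
by name, and the test suite includes a stiffness contrast showing a
fixed-step explicit Runge-Kutta integrator failing on a rate span the BDF
solver handles routinely.

Experimental conditions are named profiles: fixed values, direct functions
of time (including the linear ramp-and-hold), or gradient profiles
integrated from an initial value -- the double temperature ramp
(heat, plateau, cool) being the workhorse.  Constancy is *declared* by the
profile type, never sniffed numerically from a black-box function: a
generic function profile is treated as variable over the whole span.  That
rule makes the rate-update stop grid deterministic and testable.

Two integration formalisms are provided:

* **Continuous**: the right-hand side evaluates the calculator at the
  instantaneous condition values on every integrator step.  Exact, but it
  requires the rate law to be an explicit function of the conditions.
* **Discrete**: rate constants are precomputed at a stop grid (spacing
  $\tau_r$, covering only intervals where some condition actually varies,
  with boundary-inclusive stops) and swapped in piecewise; the integrator
  restarts cleanly at each stop so the parameter discontinuity is never
  interpolated across.  Accuracy improves monotonically as $\tau_r$
  shrinks; with a very coarse $\tau_r$ the trajectory visibly relaxes to
  the static-rate steady state between stops -- both behaviours are
  regression-tested.  The discrete route also decouples rate evaluation
  from integration, so arbitrarily expensive calculators can drive a
  simulation.

Supporting optimisations, each with its own test:

* **Slow-reaction pruning** removes reaction $i$ when
  $k_i^{\max}\, c_{\max}^{\,\mathrm{order}}\, t_{\mathrm{end}} < rtol$ --
  its most favourable possible concentration increment is below solver
  precision.  $k_i^{\max}$ is taken at the most favourable condition values
  attained anywhere in the profile, and $c_{\max}$ defaults to twice the
  total initial concentration (2-5x is the sensible range).
* **Diffusion capping** bounds bimolecular rates by the Smoluchowski
  encounter rate $k_D = 8RT/(3\eta)$ combined harmonically
  ($k_r^{-1} = k^{-1} + k_D^{-1}$), applied exactly once per rate
  evaluation and never to unimolecular steps, which have no encounter.
  The $8RT/3\eta$ prefactor is the standard diffusion-control form; it is
  deliberately overridable through the viscosity function.
* **Chunked time accumulation** splits long runs into chunks of length
  $\tau_c$, restarting the integrator at local time zero with carried-over
  concentrations; the identity
  $t_{\mathrm{global}} = n_c \tau_c + t_{\mathrm{local}}$ is exact and
  unit-tested, and global stops map to local ones by the same arithmetic.
  The motivation is that a 64-bit time variable cannot advance by less than
  $t_{\mathrm{global}} \cdot 2^{-53}$; chunking keeps the accumulating
  variable small.  The test suite verifies the bookkeeping and the
  agreement of chunked with unchunked solutions, not a literal underflow
  run, which would require deliberately extreme spans.

## Rate calculators

A calculator declares the condition names it consumes and maps their values
to one rate constant per reaction; a ConditionSet missing a declared
condition fails before integration starts.  Shipped implementations:
static (fixed vector), Arrhenius ($k = A e^{-E_a/RT}$, the workhorse), and
collision theory for bimolecular reactions
($k = N_A \sigma \sqrt{8 k_B T/\pi \mu}\, e^{-E_a/RT}$ in
dm$^3$ mol$^{-1}$ s$^{-1}$).  Physical constants are CODATA values pinned
in one table.

Because no trained activation-energy model ships with the package, demo
chemistry uses a clearly-labelled **synthetic surrogate**: homolysis
barriers from a three-entry mean bond-energy table (C-C 348, C-H 413,
H-H 436 kJ/mol), barrierless radical recombination, and an
Evans-Polanyi rule ($E_a = \max(0, E_0 + \alpha\,\Delta H)$ with
$E_0 = 50$ kJ/mol, $\alpha = 0.5$) for transfers, with typical prefactors
($10^{15}$ s$^{-1}$ unimolecular, $10^{10}$ dm$^3$ mol$^{-1}$ s$^{-1}$
bimolecular).  These values are field-plausible conventions chosen once for
the demos; they make qualitative statements (ethane decomposes at high
temperature) but no quantitative ones, and tests assert only such
qualitative invariants.

## What the synthetic fixtures do and do not show

The fixtures module provides: the five-species reversible toy network
(A+B &#8652; C, C &#8652; D, D+A &#8652; E) whose equilibrium is checkable against an
independent root-finding oracle; a hand-built ethane-pyrolysis core
network; and random stiff isomerisation networks with log-uniform rate
spans for solver stress tests.  All are deterministic under a seed.  They
exercise every code path -- balance, stiffness, variable conditions,
pruning, chunking -- but they are small and their kinetic parameters are
surrogates.  Passing tests therefore demonstrate the *machinery* (exact
conservation, correct limits, formalism agreement, reproducibility), not
agreement with any real pyrolysis product distribution, which would require
an external geometry refiner and a trained barrier model plugged into the
hooks provided.

## Numerical choices and problem sizes

Default tolerances are `rtol = 1e-8`, `atol = 1e-12` (tightened to
`1e-10`/`1e-14` where tests compare against closed forms); condition
profiles integrate at `rtol = 1e-10` with dense linear interpolation on a
2001-point grid that always includes ramp boundaries, so piecewise-linear
profiles are reproduced exactly.  Stops closer than $10^{-12}\,t_{\max}$
deduplicate.  The test and demonstration problem sizes -- H$_2$ and
two-ethane systems for sampling, networks of up to a few dozen reactions,
15-50-species random stiff networks -- were chosen as the smallest systems
that exercise every contract (enumerable move spaces make the exploration
oracle exact; two ethanes are the smallest system with bimolecular C/H
chemistry).  Direct exploration of the H$_2$ system at radius 100 with 6
parallel runs reproduces the convergence-accounting arithmetic
(5 x 6 x 100 = 3000 reactions sampled without change) with the real
sampler, not a shortcut.

## Known limitations

* Connectivity-only chemistry: no bond orders, charges, stereochemistry or
  aromaticity; species that differ only at those levels collapse to one
  identity.
* GRP geometries are starting points, not minima of any physical surface;
  quantitative kinetics requires an external refiner and barrier model via
  the provided hooks.
* The RRE is deterministic mass action; stochastic (master-equation)
  effects at small copy numbers are out of scope, as are QSSA-style model
  reductions.
* Moves spanning more than two molecules are rejected, so termolecular
  elementary steps cannot be discovered.
* Exploration cost grows with the enumeration of valid applications per
  state; the implementation is intended for focused networks (tens of
  heavy atoms), not combinatorial exhaustive search.
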