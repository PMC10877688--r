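---
title: "Methods: a spatial dynamic-FBA model of the infant gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spatial dynamic-FBA model of the infant gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsim)
```

# The model

`gutsim` simulates a community of cross-feeding gut bacteria in metabolic
detail on a rectangular lattice representing the infant colon. The default
geometry is 225 x 8 sites of 2 x 2 mm (45 x 1.6 cm, 90 mL, 0.05 mL per
site) with a timestep of 180 s; a run of 10,080 steps covers 21 simulated
days. Each site holds at most one bacterial *metapopulation* — the biomass
of one (sub)species, between 5e7 and 2e10 cells — plus per-metabolite
amounts in micromoles.

Each timestep proceeds in a fixed phase order: feeding, metabolism and
growth (populations in uniformly random order), spreading, quiescence
flags, death, colonization, Kawasaki mixing, metabolite diffusion,
advection, distal removal of metabolites and populations, recording. The
order follows the narrative structure of the underlying model and is fixed
so that a seed fully determines a run.

## Metabolism: FBA with an enzymatic constraint

Each species is described by a genome-scale metabolic model (GEM) read
from SBML in the AGORA dialect. On loading, every reversible reaction is
split into two irreversible reactions with negated stoichiometry, so all
fluxes satisfy $f \ge 0$. Reactions whose ids begin with `EX_`, `sink_` or
`DM_` are recorded as exchange reactions; those touching a single
extracellular `(e)` metabolite are coupled to the lattice pools, with the
direction producing the metabolite acting as uptake and the consuming
direction as secretion. Sink/demand reactions on intracellular
metabolites (notably the ATP demand used as the objective) are
exchange-class but are *not* coupled to the environment: venting ATP into
the colon lumen would be unphysical and would contaminate the energy
audit.

Per population and timestep the package solves

$$\max_f \; f_{\mathrm{ATP}} \quad \text{s.t.} \quad S f = 0,\;\; f \ge 0,
\;\; F_{\mathrm{in}} \le c/B_u, \;\; \textstyle\sum_r f_r \le a,$$

where $S$ is the stoichiometric matrix, $c$ the vector of site amounts
(umol), $B_u = B/10^{10}$ the population size in *population units*, and
$a$ the enzymatic constraint (default 2 umol flux per timestep per unit).
The availability bound $F_{ub} = c/B_u$ is the only reading of the
environment coupling under which total uptake $F_{\mathrm{in}} B_u$ can
never overdraw the site. Water is available in unlimited quantity and is
represented symbolically (an infinite bound), never as a large number, so
conservation checks stay meaningful. Oxygen is placed once at
initialization (0.1 umol per site by default) and is the one metabolite
exempt from advection.

**Scope of the summed-flux cap.** The cap represents finite enzyme
capacity, so it covers every real reaction — transporters and exchanges
included — but *excludes* the ATP demand pseudo-reaction that merely
meters the objective. This scope is what makes the model's yield-per-flux
accounting come out right: for a linear pathway that takes up one
substrate through an exchange, converts it in $n$ steps and secretes $k$
product molecules while yielding $y$ ATP, the optimal ATP rate under cap
$a$ is $a \cdot y/(1 + n + k)$, the basis of all closed-form fixture
optima. The scope is configurable (`"internal"`, `"all"`) for sensitivity
work.

**Growth.** Populations grow linearly with the predicted ATP production:
$\Delta B = f_{\mathrm{ATP}} \cdot 10^{-6} \cdot B_u / 10^{-15}$ cells per
step (1e-15 mol ATP to grow one cell), applied forward-Euler and capped at
the maximum population size of 2e10 cells.

**The LP backend.** The solver is a dense two-phase primal simplex
(written in C++ via Rcpp) using Bland's rule, which is cycle-free and —
more importantly here — deterministic, so whole simulations are exactly
reproducible from a seed. After maximizing ATP, a second LP minimizes the
summed flux at the fixed optimum (the parsimonious choice), which resolves
degenerate optima and makes exchange fluxes well defined. Tolerances:
LP feasibility/pivoting 1e-9; fluxes below 1e-12 umol are clipped to zero
to suppress solver round-off; site pools are clamped at zero after
exchange to absorb overdraw at the last-bit level. Tests verify the
solver against an exhaustive vertex-enumeration oracle (every candidate
active set of the polytope, solved by QR) to 1e-9 relative tolerance.

## Transport

**Diffusion** mimics mixing by colonic contractions: two substeps per
timestep, each moving 14.25% of every site's content to each of the four
nearest neighbours. Walls are no-flux on three sides (mass that would
cross a wall stays), so diffusion conserves each metabolite's total
exactly; the distal boundary loses mass only through the explicit removal
step. The per-axis displacement variance of this kernel is
$2 N p L^2$ per timestep, giving an effective diffusion coefficient

$$D = \frac{N p L^2}{\Delta t} = \frac{2 \times 0.1425 \times (0.2\,\mathrm{cm})^2}{180\,\mathrm{s}} = 6.33 \times 10^{-5}\ \mathrm{cm^2/s}.$$

The coarse (112 x 4, one substep of 7.125%, advection every second step)
and fine (450 x 16, eight substeps, two-column advection) lattice variants
rescale $N$, $p$ and the advection cadence so that $D$ in cm^2/s and the
advection speed in mm per timestep are unchanged.

**Advection** shifts all metabolites except oxygen one column distally per
timestep (2 mm per 3 min); the most distal column is cleared every step,
representing excretion. A tracer pulse fed into the six proximal columns
under the default kernel leaves the system after about 11 hours
(removal-weighted mean exit time), the model's colonic transit time.

**Well-mixed variant.** For sensitivity analysis, spatial transport can be
replaced by dividing every metabolite equally over all sites each step and
assigning all populations random non-overlapping sites.

## Population dynamics

Initialization occupies each site independently with probability 0.3 by a
population of 5e7 cells of a uniformly random roster species (about 540
populations and 2.7e10 cells on the default lattice). Populations of at
least 1e10 cells with an empty Moore-neighbourhood site split, moving half
their cells into a uniformly chosen empty neighbour. Populations at the
maximum size (2e10) set a quiescence flag and skip metabolism until they
shrink (the flag is re-evaluated every step; quiescent populations still
die, swap and wash out). Each population dies with probability 0.0075 per
step; its biomass is not returned to the pools — the FBA biomass is an
ATP proxy, so there is no meaningful carbon ledger for a corpse. Each
empty site is colonized with probability 5e-5 per step by 5e7 cells of a
uniformly random species, representing crypt reservoirs and ingested
bacteria.

Mixing is Kawasaki-style: in random site order, each site swaps its full
content (population or emptiness) with a uniformly chosen
Moore-neighbourhood site unless either partner has already swapped this
pass. The resulting population random walk has the same effective
diffusion coefficient as the metabolites (verified by mean-squared
displacement regression of a lone walker). The fast and slow sensitivity
variants run five passes per step or restrict a pass to a fifth of the
sites. The spreading neighbourhood is also Moore, matching the mixing
neighbourhood for internal consistency.

Design choices the underlying description leaves open, fixed here:
feeding happens at the start of the timestep whose index satisfies
$(t-1) \bmod 60 = 0$, so food is available from the first step; a
population that spreads may also swap in the same step's mixing pass; and
distal populations are removed after mixing.

## Thermodynamic audit

Every FBA solution can be audited against a Gibbs free-energy table
(kJ/mol at pH 7, ionic strength 0.1 M): the energy loss is
$l = \sum_i (F_{\mathrm{in}}(i) - F_{\mathrm{out}}(i)) \, E(i)$ in joules
per timestep per population unit, over the environment-coupled exchanges.
$l \ge 0$ means free energy was dissipated (plausible); $l < 0$ flags a
violation, with a tolerance of 1e-9 J absorbing LP round-off. The audit is
strictly observational — it draws no random numbers and writes nothing
back — so enabling it leaves same-seed trajectories bit-identical, which
a test asserts. Entries for 2'-FL and the GOS fractions are derived
compositely (2'-FL = lactose + fucose - water of condensation; DP$n$ =
lactose + $(n-2)$(galactose - water)), which makes the patch-added
hydrolysis reactions energy-neutral by construction. The bundled table
(`inst/extdata/energy_synthetic.csv`) carries *synthetic* values chosen to
be coherent and dissipative for the fixture metabolism; it is a
configuration input, and quantitative work should supply literature-based
values.

## Prebiotic digestion patches

Model curation is expressed as declarative patches (add/remove reaction,
set bounds, block uptake) applied in order and purely; `block_uptake`
zeroes the uptake direction of a metabolite's exchange and is the
mechanism behind the knockout experiments (disabling lactose, lactate or
1,2-PD uptake for chosen species). The prebiotic patch equips the
designated consumer with 2'-FL digestion (exchange, ABC transport at a
configurable cost of 1 ATP per molecule, intracellular fucosidase to
lactose + fucose) or GOS digestion (DP3/DP4/DP5 fractions; extracellular
stepwise cleavage DP5 -> DP4 + galactose -> DP3 + galactose; ABC
transport of DP3; intracellular hydrolysis to lactose + galactose).
Extracellular cleavage products appear in the consumer's own site pool
and cannot diffuse away mid-digestion — a known limitation shared with
the modelled system. Patched reactions conserve carbon exactly and
hydrogen/oxygen up to the water-of-condensation convention; ATP is a
virtual bookkeeping metabolite outside the element balance.

## Observables

Exchange fluxes are recorded per species, metabolite, direction and step.
The cross-feeding network aggregates the trailing 60 steps (3 h),
multiplies by the carbon content of each molecule (bundled composition
table) and keeps directed edges — species to pool for secretion, pool to
species for uptake — of at least 100 umol atomic carbon. Pools are
lattice-global. Single-timestep growth assays give a population of 5e9
cells access to one site volume (0.05 mL) of stated substrate
concentrations plus unlimited water and report $\Delta B / B$ for one
step, used to rank species on lactose, lactate, or 1,2-PD + acetate.
Butyrate-producer persistence counts the runs whose combined producer
abundance exceeds 1e10 cells at the end.

# The synthetic consortium

Because the full 20-species AGORA setup needs a database download and
cluster-scale compute, the package bundles a three-species toy consortium
with analytically known optima that reproduces the qualitative mechanism
at desk scale (a 20 x 4 lattice section, feeds scaled to its share of the
90 mL colon volume, up to 2000 steps):

* **bifido** ferments lactose to lactate + acetate and, through the
  2'-FL patch, digests 2'-FL, releasing 1,2-propanediol;
* **producer** (the butyrate producer) ferments lactate poorly and
  1,2-PD + acetate at its best yield-per-flux;
* **competitor** consumes lactose and lactate, beating the producer on
  lactate, and cannot touch 1,2-PD.

The ATP yields are design constants documented in
`make_crossfeeding_consortium()`; their yield-per-flux ordering encodes
the mechanism (prebiotic consumer prefers 2'-FL over lactose so 1,2-PD
flows as soon as it is fed; the competitor excludes the producer from the
lactate niche; 1,2-PD is the producer's winning substrate). The yields
are deliberately generous relative to real fermentative stoichiometry:
at desk scale the washout and death hazards of a 20-column lattice act on
a handful of founder lineages, and the trophic ramp must outrun them for
the competition outcome — rather than founder noise — to decide the
result. The fixtures therefore demonstrate that the *machinery*
(multi-species dFBA, transport, population dynamics, knockouts) expresses
the cross-feeding mechanism; they make no quantitative claim about any
real species, and passing fixture tests does not validate the AGORA-scale
predictions, the 21-day time course, or real abundance distributions.

Fixtures are serialized to SBML and read back through the regular loader,
so the whole pipeline — parser, normalization, patching, LP, transport —
is exercised without any network access.

# Problem sizes and runtimes in the test suite

The test suite runs entirely at desk scale, as a design choice: transport
constants are analytic or use the exact evolved kernel; the LP oracle
enumerates polytopes of at most ~20 reactions; conservation and the
mechanism checks use the 20 x 4 consortium (one 2000-step bookkeeping run;
ten 2000-step seed pairs for the mechanism, about a minute each); the
mixing-walk diffusion uses 4000 seeded walks of 25 steps on a 41 x 41
lattice. Full-scale runs (225 x 8, 10,080 steps, 20 AGORA species) are
supported through the same API — `run_simulation()` with a roster built
from downloaded AGORA SBML files — but are not part of any test.

# Known limitations

* FBA's optimality assumption: only maximal-ATP (high-yield) metabolism is
  predicted; regulated shifts to low-yield metabolism are not represented.
* The 2-D lattice discretizes a 3-D cylindrical organ; sites are equal
  volume with equal flow.
* Thermodynamics is audited, not enforced: the LP is free to pick
  solutions the audit later flags.
* Dead biomass vanishes; there is no mucin, protein or fat input, no pH
  dynamics, no host interaction.
* The bundled energy and composition tables cover the fixture metabolites
  only; AGORA-scale audits need a full table as input.
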