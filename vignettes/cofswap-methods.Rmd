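---
title: "Methods: constraint-based analysis of ICDH cofactor swapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based analysis of ICDH cofactor swapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modeling problem

When *E. coli* grows on acetate, isocitrate sits at a bifurcation: the
NADP⁺-specific isocitrate dehydrogenase (ICDH) oxidizes it to
α-ketoglutarate, producing most of the cell's NADPH but losing carbon as
CO₂, while isocitrate lyase (ICL) opens the glyoxylate shunt, conserving
carbon for biosynthesis. Swapping ICDH's cofactor to NAD⁺ removes the
dominant NADPH source and is known to depress growth. `cofswap` quantifies
the systemic consequences with flux balance analysis (FBA): every analysis
is a linear program over steady-state flux vectors,

$$\min/\max\; c^\top v \quad \text{s.t.}\quad S v = 0,\;
  v_{lb} \le v \le v_{ub},$$

with fluxes in mmol·gDW⁻¹·h⁻¹ and the biomass flux in h⁻¹. The measured
physiology of each strain enters as constraints: acetate uptake is fixed
as an equality ($lb = ub = -Q_{ac}$) and growth at the measured rate. We
chose the equality form for uptake because the workflow's objective (ATP
maintenance maximization) would otherwise always drive uptake to its
bound anyway, and an equality makes infeasibilities explicit rather than
silent.

## Strain edits

Three edits define the strains:

* **Fractional cofactor swap.** For a swap fraction $f$, the NADP⁺ and
  NADPH coefficients $a, b$ of `ICDHyr` become $(1-f)a$ and $(1-f)b$, and
  $fa$, $fb$ are added to NAD⁺ and NADH. The fraction is represented as
  mixed stoichiometry in the *single* reaction rather than as two parallel
  reactions: this keeps the LP dimension constant across a 0–100% scan and
  matches the interpretation of an enzyme population using both cofactors
  in proportion. Swaps are always expressed from the pristine
  stoichiometry (the original coefficients are stored on first edit), so
  repeated applications replace rather than compound.
* **Knockouts** zero both bounds (ΔpntAB removes `THD2pp`).
* **POR5 irreversibility.** The reversible pyruvate:ferredoxin
  oxidoreductase would otherwise fix CO₂ in reverse and synthesize C3/C4
  skeletons without the glyoxylate shunt, letting the model grow with ICL
  blocked — a spurious route. Its lower bound is clamped at zero in every
  strain preparation.

Edit order is fixed (swap, knockouts, irreversibility, bounds) so that
preparations are reproducible and idempotent.

# The iterative optimization

Maximizing the ATP maintenance drain (ATPM) under fixed growth and uptake
has, in general, a degenerate optimum: many flux distributions attain it,
some carrying arbitrary flux around internal loops. The procedure selects
a unique, loop-poor representative:

1. release ATPM to bounds (0, 50) mmol·gDW⁻¹·h⁻¹;
2. maximize ATPM (LP);
3. set the optimum as ATPM's lower bound;
4. minimize the oxygen uptake *magnitude* — since uptake is a negative
   exchange flux, this is a maximization toward zero;
5. fix the oxygen exchange at that value;
6–7. enumerate up to `n_optima` alternate ATP-optimal distributions by
   MILP;
8. select the one minimizing $\sum_i v_i^2$ (ties break to the first
   found, making the procedure deterministic);
9. pin every reaction with $|v_i|$ below the loop threshold
   (500 mmol·gDW⁻¹·h⁻¹) at its current flux, leaving larger — loop-scale —
   fluxes free;
10–11. re-enumerate and re-select.

The threshold is compared on absolute values, because a reversible loop
reaction can carry a large negative flux. The defaults (release bounds
0–50, 400 optima, threshold 500) are the workflow's standard operating
conditions; on the packaged core network the optimal face is exhausted
after a handful of support-distinct optima, so the test-suite and the
acceptance script run with `n_optima = 40`, which the enumeration never
reaches before exhaustion there.

## Alternate-optima enumeration

The MILP attaches a binary activation variable $y_i$ to every reaction,
linked by the reaction's own bounds ($lb_i\,y_i \le v_i \le ub_i\,y_i$,
big-M 1000 when a bound is infinite), constrains the objective flux to the
LP optimum (relative tolerance $10^{-6}$), minimizes $\sum_i y_i$, and
after each solution adds an integer cut
$\sum_{i \in \mathrm{supp}(v^k)} y_i \le |\mathrm{supp}(v^k)| - 1$
forcing at least one previously active reaction to zero. Consequences
worth knowing:

* solutions appear sparsest-first, and no support equals or contains an
  earlier one, so "the first $n$ optima" is well defined as discovery
  order;
* because the sparsest representative of an optimal *face* is an interior
  point of that face, the enumeration naturally returns loop-free
  representatives where a vertex enumeration could not (a 3-cycle's
  vertices sit at ±1000, its loop-free point in the middle);
* exhaustion before $n$ is expected and reported, not an error; node- and
  time-limits mark results as partial instead of failing.

The branch and bound explores binaries depth-first, zero branch first,
most-fractional branching with lowest-index tie-breaks — fully
deterministic, which the bit-identical re-run tests rely on.

## The LP engine

The package carries its own dense two-phase bounded-variable simplex
(`solve_lp()`): phase 1 drives signed artificial columns to zero, phase 2
optimizes with artificials pinned; pricing is Dantzig's rule switching to
Bland's rule after a run of degenerate pivots, so cycling terminates.
Tolerances: pivot $10^{-9}$, feasibility declared when the phase-1
objective is below $10^{-7}$; test comparisons use $10^{-6}$. The engine is
validated against an independent brute-force oracle that enumerates every
basic solution of random bounded LPs, and — during development — against an
external interior-point/dual-simplex implementation, which agreed to
$10^{-12}$ on the fixture optima frozen in `core_acetate_reference()`.

# Sub-optimal sampling

`sample_fluxes()` models sub-optimality of *growth*, not energy: biomass
is bounded below by 90% of the measured rate (and above by the measured
rate), acetate uptake stays fixed, and ATPM is released to (0, 50) rather
than held at its optimum. The artificially centered hit-and-run chain
starts from the flux-variability extreme points (2 × reactions warmup
points), moves one stored point per step along a direction from a randomly
chosen point through the running center, and retains every `thin`-th
iterate (default 100; the uniformity test on a one-dimensional segment
uses 5, since there each step already redraws uniformly over the whole
chord). Directions are differences of feasible points, hence lie in the
null space of $S$, so $S v = 0$ holds exactly along the chain; bounds are
enforced by the step-size limits. The default sample count is twice the
reaction count. Reversible reactions are sampled as single signed
dimensions.

Note one consequence of releasing ATPM: flux patterns that are FVA-zero
when ATPM is held at its optimum (e.g. the soluble transhydrogenase after
a full swap) *can* appear in samples, because the sampled polytope has
energetic slack. The consistency test therefore checks samples against the
FVA ranges of the sampling polytope itself.

# Accounting conventions

Net turnover of metabolite $i$ is $\varphi_i = \tfrac12 \sum_j
|S(i,j)\,v_j|$; at steady state this equals both the summed production
terms and the negated consumption terms, which the suite asserts on random
null-space vectors. "Production of a cofactor" is per reaction and per
reduced species with the sign of $S(i,j)\,v_j$: a transhydrogenase
appears as a producer on exactly one of the NADPH/NADH ledgers depending
on its flux direction. Growth-associated ATP is total ATP turnover minus
the maintenance flux. Percentages are reported as $100\,v/Q_{ac}$,
sign-preserving. Accounting always uses the *strain-edited* stoichiometry;
using the pristine matrix would misattribute the swapped ICDH's product.

# The synthetic networks

`core_acetate_model()` is a ~30-reaction condensation of acetate
metabolism: acetate activation (2 ATP per acetate, the AMP-forming
ledger), TCA reactions with explicit NAD(P)H/ATP stoichiometry, the
glyoxylate shunt, PEP-synthase/PEP-carboxylase anaplerosis, a
gluconeogenesis lump, oxidative and non-oxidative pentose-phosphate
lumps, both malic enzymes, PntAB (charged 0.25 ATP per NADPH as a
proton-motive-force equivalent) and UdhA, POR5 with an NADPH-driven
flavodoxin reductase, oxidative phosphorylation at P/O 2 (NADH) and 1
(FADH₂), an ATPM drain, and a biomass reaction whose precursor, ATP (50
mmol·gDW⁻¹) and NADPH (12 mmol·gDW⁻¹) coefficients sit in the
physiological range for *E. coli* — biomass requires NADPH explicitly so
swap effects propagate to growth. The fumarase isozyme pair provides both
a free internal loop and a degenerate-optimum structure; the reversible
POR5 provides the spurious carbon-fixation route whose correction makes
ICL essential.

The fixture reproduces the *mechanisms* the analyses probe — which
transhydrogenase activates on which side of the swap, how the partition
and maintenance flux move, the three regimes (rise, plateau, collapse) of
growth versus ICL partition — but none of the genome-scale *magnitudes*:
with only ~30 reactions, growth is far cheaper than in a full
reconstruction, so quantities like the maintenance-flux ratio between
swapped and wild-type strains, or the numerical position of the optimal
partition vertex, land at fixture-scale values. Passing tests therefore
demonstrate correctness of the machinery and direction of the biology,
not numeric agreement with genome-scale runs, which require supplying an
external SBML reconstruction through `read_sbml()`.

Reference optima for the fixture (`core_acetate_reference()`) were frozen
from two independent solvers agreeing to twelve digits and are asserted at
$10^{-9}$.

`loopy_toy_model()` and `degenerate_optima_model(k)` isolate the two
degeneracy phenomena (internal cycles; parallel equivalent routes with
exactly $k$ support-distinct optima) for targeted tests.

# Other design choices

* **Biomass reaction choice.** When a model carries several biomass
  variants, `find_biomass()` takes the first match and every function
  accepts an explicit `biomass_reaction`/`objective` override.
* **FVA reporting.** Strain FVA is run with growth and uptake fixed *and*
  ATPM lower-bounded at its optimum (a flag in the workflow): without the
  energy constraint most redox-flexibility conclusions (e.g. a zero UdhA
  maximum) would not be decidable.
* **Dense matrices.** Networks at fixture scale (and the LP bases the
  simplex factors) are far below the size where sparse storage pays; `S`
  is a plain dense matrix with dimnames.
* **Exchange-id dialects.** `EX_ac(e)` and `EX_ac_e` are accepted
  interchangeably everywhere a reaction id is looked up.
* **Grid infeasibilities** in robustness and phase-plane scans are
  recorded with their status, never dropped or interpolated.

# Known limitations

* No kinetics or regulation: ICDH phosphorylation and NADPH product
  inhibition, which in vivo tune the branch point, are outside the
  steady-state formalism.
* The MILP enumeration is exact but pure R; on genome-scale models with
  thousands of binaries it would need the configured node/time caps and
  would return partial enumerations flagged as such.
* Hit-and-run convergence is not formally diagnosed beyond determinism
  and range checks; modes of sampled histograms should be read
  qualitatively.
* The SBML layer covers L3/FBC v2 and L2 kinetic-law bounds — the subset
  needed for flux models — not the full SBML feature set.
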