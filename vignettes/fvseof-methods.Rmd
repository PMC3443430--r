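---
title: "Identifying gene amplification targets by flux variability scanning under grouping reaction constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying gene amplification targets by flux variability scanning under grouping reaction constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvseof)
```

## The problem

Knockout targets for strain engineering are easy to simulate — constrain a
flux to zero and re-optimise.  Amplification targets are harder: in a
constraint-based model, a reaction worth over-expressing is one whose flux
must *rise* as the cell is pushed to make more product, and single optimal
flux vectors are unreliable evidence for that because genome-scale linear
programs have vast spaces of alternative optima.  This package implements
flux variability scanning based on enforced objective flux (FVSEOF): instead
of one solution per condition, it tracks the *attainable flux range* of each
reaction while the product formation rate is artificially stepped from its
minimum to near its theoretical maximum, and it shrinks the solution space
beforehand with grouping reaction (GR) constraints derived from genomic
context — reactions that evolution keeps together (conserved neighbourhood,
gene fusion, co-occurrence) are forced to be on or off together and, when
their positions in the carbon flow agree, to run at comparable scale.

## The model

The metabolic state is a flux vector $v$ over reactions $J$ subject to
steady-state mass balance and bounds,

$$\sum_{j \in J} S_{ij} v_j = b_i, \qquad \alpha_j \le v_j \le \beta_j,$$

with $b_i = 0$ for every intermediate metabolite, default bounds
$\pm 1000\ \mathrm{mmol\,gDCW^{-1}h^{-1}}$, irreversible reactions
non-negative, and the carbon-source uptake fixed at
$10\ \mathrm{mmol\,gDCW^{-1}h^{-1}}$ during the analysis.

**On/off couplings.** Each reaction group shares one binary indicator:
$y(v_1) = y(v_2)$ with activation bounds $y\,\alpha_j \le v_j \le
y\,\beta_j$.  All members silent or all members free.  A deliberate
consequence of the activation form: the static model bounds of a grouped
reaction are *replaced* by the activation bounds (a positive lower bound
would otherwise contradict the off state), so the solver widens a grouped
member's variable bounds to include zero unless a runtime override pins
them.

**Flux-scale couplings.** For a group pair whose flux-converging indices
agree (below), the uptake-normalised fluxes $v^n_j = v_j / v_{\text{uptake}}$
must stay within $\delta$ of their common midpoint
$m = (v^n_1 + v^n_2)/2$:

$$\sqrt{(v^n_1 - m)^2 + (v^n_2 - m)^2} \le \delta .$$

Because the deviations of two numbers from their own midpoint are equal and
opposite, the left side is identically $|v^n_1 - v^n_2| / \sqrt{2}$, so the
coupling is *exactly* the linear band
$|v_1 - v_2| \le \delta \sqrt{2}\, v_{\text{uptake}}$.  The package uses
this linear form; nothing is approximated, and the constraint stays valid
when the uptake flux is a variable rather than a constant.  The default
$\delta = 0.3$ is the recommended flux-level constant; at uptake 10 it
allows the members of a coupled pair to differ by at most
$\approx 4.24\ \mathrm{mmol\,gDCW^{-1}h^{-1}}$.

**Flux-converging (CxJy) indexing.**  Whether two grouped reactions are
scale-comparable is decided by where they sit in the carbon flow.  Each
indexable reaction gets entries $C_x J_y$: $x = N_C/2$, half the summed
carbon atoms of its primary (non-cofactor) participants, and $y \in
\{A,B,C,D\}$ counting how many *flux-converging metabolites* — metabolites
where two routes that split at a common ancestor rejoin, detected by a
vertex-disjoint-paths test on the cofactor-free metabolite digraph — lie
strictly upstream on a simple route from the carbon source (0/1/2/3, higher
counts clamp to D).  Routes through pyruvate carry an `E` suffix.  A
reaction reachable by routes with different counts keeps one entry per
distinct tag, and two reactions are index-equivalent when their entry *sets*
are equal — the strictest reading of equality, chosen because a weaker one
would emit couplings the index analysis cannot justify.  Two interpretation
points were genuinely open and are fixed here as follows: a converging
metabolite that is the reaction's own substrate is *not* counted as passed
(counting is strictly upstream), while pyruvate as the terminal substrate
*does* set the `E` flag (a flux entering through pyruvate is derived from
it).  The raw carbon sum $N_C$ is reported alongside $x$ because the two
conventions for $C_x$ found in practice differ by exactly this factor of
two.

## The scan

1. With GR constraints active and uptake fixed, minimise and maximise the
   product flux: $v^{\text{initial}}$ and $v^{\max}$.
2. Build the schedule $v^{\text{enforced}}(k) = v^{\text{initial}} +
   \tfrac{k}{n}(v^{\max} - v^{\text{initial}})$ for $k = 0, \dots, n-1$
   ($n \ge 10$): from the unenforced baseline up to a value adjacent to,
   but below, the theoretical maximum.  The $k=0$ baseline is included so
   the slope regressions are anchored at the unenforced state.
3. At each level, fix the product flux (both bounds), maximise growth
   $Z^{\text{opt}}(k)$, then fix $v_{\text{biomass}} = 0.95\,
   Z^{\text{opt}}(k)$ — the printed equality; a `growth_at_least` switch
   offers the common $\ge$ relaxation, off by default — and minimise and
   maximise every intracellular (non-exchange) reaction flux.

Each level is assembled and solved independently; nothing is warm-started,
so no result can depend on visit order.  A level that is infeasible (which
can genuinely happen when an on/off group forces a gap in the attainable
product fluxes, or adjacent to the theoretical maximum) truncates the scan
at the last feasible level with an explicit warning.

## Targeting criteria

Per reaction and level, the flux bias and flux capacity are
$V_{avg} = (V'_{\max} + V'_{\min})/2$ and $l_{sol} = V'_{\max} -
V'_{\min}$, and $q_{\text{slope}}$ is the ordinary-least-squares slope of
$V_{avg}$ against the enforced flux.  The signs of the $V_{avg}$ and
$l_{sol}$ trends, each trichotomised with a flat band $\varepsilon$,
classify the reaction into nine types: 1–3 rising bias (amplification
candidates), 4–6 falling, 7–9 flat or oscillatory.  Within each triple the
capacity trend (shrinking / flat / growing) orders the sub-type; only the
triple membership carries scientific meaning, the sub-index is a documented
convention.  Types 1–3 are split into **strong** (bias non-decreasing at
every consecutive step pair, positive overall slope) and **weak** (positive
overall slope with a local dip).  Ranking keeps types 1–3, drops the
biomass and target reactions, and orders by strength, then ascending mean
$l_{sol}$ — a narrow range means the predicted flux is most likely realised
— then descending $q_{\text{slope}}$, then reaction id as the deterministic
tie-break.

Reversible reactions can carry their signal in the negative direction: a
reaction whose range stays non-positive while its bias grows more negative
is an amplification candidate of the *reverse* direction; its series is
sign-flipped and the report carries `direction = "reverse"`.

## Numerical choices

* Feasibility tolerance $10^{-6}$, bound slack $10^{-9}$, binary
  integrality $10^{-6}$ — standard LP practice.
* The flat band defaults to $\varepsilon = 10^{-6} \times$ uptake rate,
  which makes the classification invariant under a uniform rescaling of all
  fluxes (a property the test suite checks at a factor of ten).
* The production solver is a branch-and-bound on the group binaries over an
  LP relaxation solved with `boot::simplex`.  A presolve stage converts
  singleton rows to bounds, substitutes fixed variables, and eliminates
  forcing rows (rows whose attainable extreme equals their right-hand
  side); beyond speed, this removes the degenerate zero-width rows on which
  the underlying simplex routine can stall.  When the reduced objective is
  identically zero the kernel substitutes a benign feasibility objective.
* The verification oracle enumerates all $2^G$ binary patterns and solves
  each continuous problem with `pracma::linprog` in standard form — a
  different simplex codebase and a different integer strategy, exact
  because the packaged networks keep $G$ small.  Equality between the two
  routes, for every reaction at every scan step, is part of the shipped
  checks.
* Degenerate alternative FBA optima are accepted as-is; every downstream
  statistic is computed from ranges, never from a single solution vector —
  that is the point of the method.

## What the toy networks emulate — and what they do not

`make_toy_model()` builds three networks.  The `glycolysis_like` topology
mirrors the canonical upper-glycolysis motif: a C6 source, an
aldolase-style split into two trioses, a rejoin at the
glyceraldehyde-3-phosphate analogue (the single flux-converging
metabolite), a PEP/pyruvate lower half with two isoenzyme-style parallel
kinases, a product branch, a biomass drain competing for the same
precursors, and a pyruvate-overflow secretion (without which fixing growth
at 95 % of its optimum would be infeasible — every flux would be uniquely
determined, a failure mode of early drafts of this network that real
overflow metabolism does not share).  Its analytic behaviour is fully hand
computable: theoretical product maximum $2 \times$ uptake, growth line
$(20 - p)/2$, isoenzyme band $\pm \delta\sqrt{2} \cdot 10 / 2$ around the
even split.  Seeded variants perturb only upper bounds, uniformly in
$[30, 1000]$ — never below the carbon-limited maximum flux of 20, so every
analytic yield survives, and never the stoichiometry.

These fixtures validate the machinery, not the biology: they have a handful
of reactions, one converging metabolite, complete formulas, no compartments
beyond a boundary, and groups that are correct by construction.  Passing
tests therefore demonstrate that the optimisation, indexing and ranking are
implemented exactly — not that GR constraints improve predictions on a real
genome-scale model, which requires a curated model and a genomic-context
group file of real provenance.  On genome-scale inputs the pure-R simplex
kernel is also the practical bottleneck; the layer is deliberately small so
a faster LP backend can replace it behind the same interface.

Problem sizes used throughout the shipped tests and the acceptance script —
networks of 3–11 reactions, 10 scan levels, 10–20 seeded replicates — were
chosen so the brute-force oracle enumeration stays exact and instantaneous.

## Known limitations

* GPR logic is not evaluated; gene lists are annotation carried to the
  report.
* Loopless FVA, thermodynamic constraints and flux sampling are out of
  scope.
* Route enumeration for the CxJy index caps at $10^4$ simple routes per
  reaction (with a warning); on highly connected genome-scale networks the
  index should be restricted to a pathway scope, which the `scope` argument
  of `build_gr_constraints()` supports.
* The nine-type sub-indexing within each triple is a fixed documented
  convention; other assignments of the integers 1–9 are defensible.
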