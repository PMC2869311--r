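---
title: "The coupled genetic/epigenetic hierarchy model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled genetic/epigenetic hierarchy model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epihier)
```

## The model

`epihier` simulates cellular identity as attractors of two coupled spin
lattices living on a binary hierarchy (Cayley tree) of master-regulator
gene modules. The root module governs the pluripotent (ES) state; each
node's two children are the lineages it can differentiate into; leaves
are terminally differentiated identities. Module `i` carries

* an **epigenetic spin** $S_i^{ep} \in \{-1, 0, +1\}$: silenced by
  repressive histone marks or DNA methylation, bivalently marked
  (poised but not transcribed), or open; and
* an **expression spin** $S_i^{gen} \in \{0, 1\}$: off or on.

The cell cycle is split into two phases. During **interphase** the
epigenome is frozen and expression equilibrates; during **telophase**
(chromatin decondensing after division) the protein environment
rewrites the epigenetic marks. Each phase is a Metropolis Monte Carlo
equilibration of one lattice with the other lattice's *averages* held
fixed, and the converged averages are handed to the next phase
(`run_cycle()` = `run_interphase()` then `run_telophase()`).

### Telophase Hamiltonian (epigenome rewriting)

With $p_j = \langle S_j^{gen}\rangle \cdot \mathbf{1}[\langle
S_j^{gen}\rangle > a]$ the effective protein activity of module $j$,

$$E_{telo} = \sum_j p_j \Big[ -G\, S_j^{ep}
 \;+\; G \!\!\sum_{i \in \{par(j),\, sib(j)\}}\!\! S_i^{ep}
 \;+\; G \!\!\sum_{i \in ch(j)}\!\! |S_i^{ep}|
 \;+\; H \!\!\sum_{i \in distal(j)}\!\! S_i^{ep} \Big].$$

The four terms are the four epigenetic rules: proteins (1) keep their
own module open, (2) put repressive histone marks on the modules of the
immediate progenitor and sibling, (3) keep the immediate progeny
bivalent (poised), and (4) methylate — long-range — every module that
is neither their own nor one of its descendants. The distal set
includes the parent and sibling, which therefore feel both the
short-range histone field ($G$) and the methylation field ($H$); the
fields add. This is the reading of the rules we adopted for the
otherwise ambiguous overlap between rules 2 and 4: the textual
definition of rule 4 ("competing lineages or less differentiated
states in the same lineage") covers the progenitor and sibling, and
rule 4 must be long-ranged for the model's central mechanism to work
(see *Rule-4 range* below).

### Interphase Hamiltonian (expression)

$$E_{inter} = -F \sum_i \big(\langle S_i^{ep}\rangle - b\big)\,S_i^{gen}
 \;+\; J \!\!\sum_{(i,j)\ \mathrm{NN}}\!\! S_i^{gen} S_j^{gen}.$$

Expression is favoured exactly when the epigenetic availability exceeds
$b$; heterochromatin ($\langle S^{ep}\rangle = -1$) represses more
strongly than bivalent chromatin ($0$), which is what makes bivalency
"poised". The $J$ term is the mutual repression between
nearest-neighbour modules (parent—child and sibling pairs), the
genetic tug-of-war that forces a *choice* of identity.

The algebra above is this package's contract: the minimal form that
realizes the stated rules (number and role of the terms, signs,
heterochromatin repressing more strongly than bivalent chromatin).
`a` is implemented as a protein-activity threshold — its operational
definition — rather than as an offset inside the epigenetic terms.

### Parameters

| name | default | meaning |
|------|---------|---------|
| `G`  | 25      | histone-mark field strength (rules 1–3), units of $1/\beta$ |
| `H`  | 40      | DNA-methylation field strength (rule 4) |
| `F`  | 2000    | epigenome→expression coupling (rule 1′) |
| `J`  | 3000    | mutual repression (rule 2′) |
| `a`  | 0       | minimal expression for a protein to act on chromatin |
| `b`  | 0.3     | minimal availability $\langle S^{ep}\rangle$ for expression |
| `beta` | 1     | inverse temperature; sets the scale of G, H, F, J |
| `updates_per_phase` | 50{,}000 | Metropolis single-site updates per phase |

Qualitative behaviour requires $H > G$ (methylation beats histone
marks), $J > F \gg H, G$, $0.1 < b < 0.5$ and $0 \le a < 0.6$;
`model_parameters()` warns outside this region. `b` must exceed the
typical fluctuation of the phase averages ($\sim 0.1$) or bivalent
modules fire spuriously; `sensitivity_scan()` exposes both kinds of
degradation.

### Ergodicity breaking is the mechanism, not a bug

At the default couplings ($\beta J = 3000$) the interphase chain cannot
cross the barrier between the degenerate single-module minima of two
open, mutually repressive modules: whichever minimum the randomly
initialized chain falls into first is the phase's outcome. This broken
ergodicity *is* the stochastic fate choice of the model — e.g. the
winner of the battle between a de-silenced module and the incumbent
identity, or the three-way fate choice of an ES cell. Consequently the
Monte Carlo engine can only be validated against exact Boltzmann
enumeration where the chain mixes; the test suite draws random
parameters at $O(1/\beta)$ coupling scale for those oracle
comparisons (trees of ≤ 3 nodes, ≤ 27 configurations, agreement
within 0.02), and checks the sharp-coupling regime through its
deterministic field-driven limits and attractor properties instead.

### Numerical choices

* **Burn-in and averaging.** Averages accumulate over the second half
  of the updates; the first half is burn-in. Averaging from the first
  update instead would only add a small bias on free sites at 50,000
  updates.
* **Convergence flag.** A phase reports `converged` when the running
  averages of its 3rd and 4th quarters agree within `tol` at every
  site. Field-free (bivalent) sites fluctuate with a quarter-average
  scatter of 0.04–0.09 at the default update budget — the same
  $\sim 0.1$ scale the model's own validity condition on `b` cites —
  so `tol` defaults to 0.15: above that intrinsic noise floor, far
  below the 0.3/0.5 decision thresholds. A tolerance much below 0.1
  would declare honest equilibrations unconverged at the standard
  update budget.
* **Label thresholds.** $\theta_{gen} = \theta_{ep} = 0.5$: "expressed"
  means $\langle S^{gen}\rangle > 0.5$, open/silenced mean
  $\langle S^{ep}\rangle$ beyond $\pm 0.5$, bivalent is the middle
  band. 0.5 bisects the attractor values ($\approx 0, \pm 1$) with a
  margin several times the fluctuation scale.
* **Proposal law.** A move picks a site uniformly and proposes one of
  its alternative values with equal probability (for a ternary site in
  state 0: $-1$ or $+1$ with probability $\tfrac12$ each), accepted
  with probability $\min[1, e^{-\beta \Delta E}]$.
* **RNG.** All randomness flows through R's RNG (the compiled engines
  use `unif_rand`), so a single `set.seed()` reproduces everything.
  Replicate runs derive one sub-seed per trajectory from the root
  seed, making each trajectory independently re-runnable.

## One cell cycle, and the ordering of phases

`run_cycle()` performs interphase first (expression read off the
current epigenome), then telophase (the new proteins rewrite the
epigenome). This ordering is forced by the reprogramming protocol: a
de-silencing perturbation edits the *epigenome*, and the edited
epigenome must be transcribed before the incumbent identity's proteins
get a chance to re-silence it — running telophase first would erase
every perturbation unseen (the perturbed module's field from the
incumbent proteins is $+G+H$) and no reprogramming could ever occur.

## Differentiation

With ES-maintenance medium present (the default rule set) the ES state
is a strict fixed point. The medium's withdrawal is modelled by the
`lif_absent` switch: the root module's rule-3 action on its two
children becomes rule-1-like positive marking, so after one telophase
both progeny modules are open and the next interphase is a symmetric
three-way battle (root, left child, right child) that the mutual
repression $J$ resolves into exactly one winner —
`simulate_self_differentiation()` counts the resulting trichotomy.
On the two-level tree the three contenders are exactly exchangeable
and the outcome is uniform to within sampling error. On deeper trees
the random initialization of the expression lattice breaks the
symmetry slightly in favour of self-renewal: each lineage contender
is transiently repressed by its own poised progeny (whose randomly
initialized spins take a few sweeps to turn off), whereas the root's
only neighbours are the contenders themselves. The package therefore
demonstrates the equal-chance trichotomy on the minimal two-level
hierarchy and documents the depth effect here rather than hiding it;
an all-off initialization would restore exact symmetry at any depth
but would contradict the stated random-initialization algorithm and
shift every identity-battle probability in the model.

A differentiation **cue** (`cue_spec()`) is an additive rule-1-like
telophase field of strength $s\cdot G$ on the module of the desired
progeny. Against the maintenance-medium background the cued child's
chromatin opens when the cue overcomes the rule-3 bivalence penalty;
the per-cycle commitment probability rises from 0 to its plateau over
a narrow strength window around $s \approx 1$ (the crossover where the
cued module's equilibrium availability crosses `b`, smeared by the
Monte Carlo noise of the averages), and the number of uncommitted
progenitors decays exponentially with a strength-dependent rate.
Committed cells never enter the un-cued lineage (its chromatin stays
bivalent), which is the model's account of high-fidelity forward
programming. Because the plateau is reached within a few percent above
the crossover, "strength-dependent" is a threshold phenomenon here:
the package's tests probe strengths spanning the crossover
(0.96–1.0), where the measured commitment rate climbs from ~0.001 to
~0.45 per cycle, rather than deep saturation where it is flat.

## Reprogramming

`simulate_trajectory()` implements the reprogramming factor protocol:
start from a terminally differentiated leaf; each cycle de-silence one
uniformly chosen silenced module (`perturbation_policy()`), run the
cycle, and classify the change of the dominant expressed set:
`return`, `dedifferentiation` (to the parent), `transdifferentiation`
(to the sibling), `death_arrest` (nothing expressed, or two modules
that are not hierarchy neighbours — conflicting identities), or
`none`. Two stopping rules operationalize the absorbing outcomes:

* **reprogrammed** — the dominant set is exactly the root and one
  perturbation-free confirmation cycle preserves it ("stable"
  activation of the endogenous ES module; transient root activations
  fail the confirmation and the trajectory continues);
* **dead_arrested** — a death/arrest classification that persists
  through one perturbation-free cycle. The persistence requirement
  matters: co-expression of the incumbent with a de-silenced
  *ancestor* is a legitimate transient (the ancestor is re-silenced by
  the incumbent's methylation field, the incumbent survives), whereas
  co-expression with a different lineage silences both sides and is
  genuinely absorbing.

`max_cycles` defaults to 200; truncations are reported as a separate
outcome and counted as unsuccessful. One trajectory is one cell; there
is no population bookkeeping.

### Rule-4 range

`rule4_range = "nearest"` restricts the methylation field to the
parent and sibling. This ablation removes the only long-range
constraint, so a de-silenced root module is no longer re-silenced by a
deep incumbent's proteins and stable root expression becomes possible
within the first cycles — the signature the full model forbids (root
activation before the final step is transient). The package keeps the
ablation as a switch because it is the model's own control experiment
for why the methylation constraint must be long-ranged.

## Multi-gene modules

In the `genes_per_module = g` variant each module comprises `g`
genes with their own spins; genes do not interact directly. A module
acts — on the epigenome, and through mutual repression — only when
*all* its genes are expressed (combinatorial control): telophase
fields are computed from module activities (the minimum gene
expression, thresholded at `a`) and applied identically to each gene
of a target module; the interphase $J$ penalty couples the products of
neighbouring modules' gene spins. Perturbations act gene-wise (`k`
silenced genes per telophase, default 12 for $g = 3$). With $g = 1$
the variant reduces to the base model.

Because a module only fires when all $g$ of its genes are de-silenced
within a single cycle (the incumbent's methylation re-silences
stragglers every telophase), single-gene perturbation ($k = 1$)
can never complete a 3-gene module and reprogramming is structurally
impossible; large $k$ completes unrelated-lineage modules so often
that conflict death dominates. Successful reprogramming at
intermediate $k$ is therefore possible but rare, and individual genes
of unrelated lineages fire transiently along the way without their
modules ever completing.

## Analyses

`four_point_correlation()` computes, over (successful) trajectories,
the joint probability that unit $i$ switches off while unit $j$
switches on across a lag of $\Delta t$ cycles, from the binarized
expression series:
$C(i,j,\Delta t) = \langle \delta(S_i(t),1)\,\delta(S_i(t{+}\Delta t),0)\,
\delta(S_j(t),0)\,\delta(S_j(t{+}\Delta t),1) \rangle$.
The time unit is one cell cycle. Two normalizations are reported: the
plain average over all valid origins (`C`) and the probability
conditional on $i$ actually switching off (`C_conditional`); both
conditioning conventions are defensible definitions of the statistic,
so both are exposed. High values concentrate on hierarchy-adjacent
pairs — the observable signature of the nearest-neighbour
reprogramming paths.

`event_census()` tabulates events and outcomes;
`sensitivity_scan()` re-runs reduced efficiency estimates over a
parameter grid and raises qualitative flags (early stable root
expression when $H \le G$; fixed-point/trichotomy degradation when
`b` drops below the fluctuation scale).

## Problem sizes used by the test suite and acceptance script

The package's own empirical checks run at sizes a desk machine
handles in minutes, chosen once as the smallest sizes at which the
corresponding effects are statistically resolvable: 3-level
reprogramming efficiency at 1,000–5,000 trajectories (the printed
experiment's own replicate range), 4- and 5-level depth comparisons at
1,500–2,000 trajectories (enough to separate the 3-level rate from
the deeper levels' near-zero rates by exact binomial intervals),
trichotomy at 3,000 one-cell decisions, oracle comparisons on ≤ 27
configurations, and multi-gene runs at a few hundred trajectories per
perturbation width. The multi-gene success-rate comparison across
perturbation widths is the one analysis whose full confirmation needs
population scales beyond a desk run (the intermediate-width success
rate is of order $10^{-4}$); the package tests the structurally
certain parts (no successes at $k=1$, faster conflict death at
$k=22$) and reports the rest as estimates with intervals.

## What the simulations do and do not show

All inputs are generated by the model itself; there is no external
data. The synthetic trajectories emulate the logic of transcription
factor induced reprogramming — random epigenetic perturbation, identity
battles, nearest-neighbour paths, rare success — under exchangeable
modules, a strict binary hierarchy, one perturbation policy for every
cell and cycle-synchronous dynamics. They do not model real gene
identities, heterogeneous factor dosage, variable cycling rates,
module-specific couplings, or any molecular mechanism of the factors;
passing tests certify the model's internal consistency and the
phenomenology described above, not claims about any particular
biological system.
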