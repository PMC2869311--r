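# epihier

Monte Carlo simulation of cellular identity as attractors of coupled
genetic and epigenetic regulatory networks, for computational and
systems biologists studying differentiation and transcription-factor
induced reprogramming (iPS derivation).

## The model

Master-regulator gene modules sit on a complete binary hierarchy (a
Cayley tree): the root governs the embryonic-stem (ES) state, each
node's two children are the lineages it can differentiate into, leaves
are terminal identities. Module *i* carries an epigenetic spin
S<sub>i</sub><sup>ep</sup> ∈ {−1, 0, +1} (silenced / bivalent / open
chromatin) and an expression spin S<sub>i</sub><sup>gen</sup> ∈ {0, 1}.
The cell cycle alternates two Metropolis equilibrations:

* **interphase** — expression under the frozen epigenome,

  E = −F Σ<sub>i</sub> (⟨S<sub>i</sub><sup>ep</sup>⟩ − b) S<sub>i</sub><sup>gen</sup>
  + J Σ<sub>⟨i,j⟩</sub> S<sub>i</sub><sup>gen</sup> S<sub>j</sub><sup>gen</sup>,

  an Ising-like Hamiltonian whose J term is the mutual repression
  between nearest-neighbour (parent–child and sibling) modules;

* **telophase** — epigenome rewriting by the protein environment
  p<sub>j</sub> = ⟨S<sub>j</sub><sup>gen</sup>⟩·1[⟨S<sub>j</sub><sup>gen</sup>⟩ > a],

  E = Σ<sub>j</sub> p<sub>j</sub> [ −G S<sub>j</sub><sup>ep</sup>
  + G Σ<sub>i∈{par,sib}</sub> S<sub>i</sub><sup>ep</sup>
  + G Σ<sub>i∈children</sub> |S<sub>i</sub><sup>ep</sup>|
  + H Σ<sub>i∈distal</sub> S<sub>i</sub><sup>ep</sup> ],

  a Potts-like Hamiltonian encoding four rules: self-maintenance,
  silencing of progenitor and sibling, bivalent (poised) marking of
  progeny, and long-range DNA methylation of all non-descendant
  modules.

Standard parameters: G = 25, H = 40, F = 2000, J = 3000, a = 0,
b = 0.3, β = 1, 50,000 updates per phase. At these couplings the
mutual-repression barrier is unbridgeable, so the randomly initialized
chain falls into one of the degenerate single-identity minima — that
broken ergodicity is the model's stochastic fate choice.

Reprogramming factors are modelled as random de-silencing: each cycle
one uniformly chosen silenced module is switched to open chromatin,
the cell re-equilibrates, and the change of dominant expressed module
is classified (return, de-differentiation, trans-differentiation,
death/arrest). Reprogramming to the ES state succeeds only through
rare chains of nearest-neighbour steps, so the success rate falls
steeply with hierarchy depth (~2.4% at 3 levels, ~10⁻⁴ at 4,
~0 at 5 in this implementation). A multi-gene variant (g genes per
module, all-genes-required activity, gene-wise perturbation) and a
four-point temporal correlation analysis of the reprogramming paths
are included.

## Worked example

```r
library(epihier)
topo <- build_hierarchy(3)          # 3-level hierarchy, 7 modules
pars <- model_parameters()          # standard parameter set
cell <- make_terminal_state(topo, leaf = 3, pars)
print(cell)
#> cell_state (7 modules)
#>   expressed: 3
#>   open:      3
#>   bivalent:
#>   silenced:  0 1 2 4 5 6

tr <- simulate_trajectory(topo, pars, seed = 42)
tr$cycles[, c("cycle", "perturbed", "event", "dominant")]
#>   cycle perturbed        event dominant
#> 1     1         0 death_arrest      0;3
#> 2     2                   none        3
#> 3     3         4       return        3
#> 4     4         1       return        3
#> 5     5         6 death_arrest      3;6
#> 6     6           death_arrest
```

This cell starts terminally differentiated (module 3 expressed and
open, the six other modules silenced). Cycle 1 de-silences the ES
module (0): it is transiently co-expressed with the incumbent (`0;3`)
but re-silenced by the long-range methylation rule at cycle 2 — the
endogenous ES module can only activate transiently before the final
step. Cycles 3–4 de-silence the sibling (4) and progenitor (1); the
incumbent wins both expression battles (`return`). Cycle 5 de-silences
module 6 from the competing lineage: the conflicting co-expression
(`3;6`) silences both sides and the cell is absorbed into the
dead/arrested state.

```r
eff <- estimate_efficiency(topo, pars, n = 400, seed = 7)
print(eff)
#> efficiency_estimate: 14/400 reprogrammed (3.500%), 95% CI [1.926%, 5.803%]
#>
#>       reprogrammed      dead_arrested max_cycles_reached
#>                 14                386                  0
```

Most cells die or arrest; a few percent reach the stable ES state, via
de-/trans-differentiation chains only (at larger n the rate settles
near 2.4%). `simulate_self_differentiation()`,
`simulate_cued_differentiation()`, `simulate_multigene_reprogramming()`,
`four_point_correlation()` and `sensitivity_scan()` cover the other
experiments; `exec/epihier` runs any of them from a config file
(`inst/extdata/example-reprogram.cfg`).

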