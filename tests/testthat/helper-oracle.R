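# Independent brute-force Boltzmann oracle for tiny systems.
#
# Enumerates every configuration of <= a few sites and computes exact
# thermal averages from the partition function. The energy callbacks
# used with it in the tests are written from first principles (direct
# sums over rule terms), independent of the package's field
# construction, so oracle and implementation can disagree.

exact_boltzmann_averages <- function(energy_fn, state_space, beta) {
  grid <- expand.grid(state_space, KEEP.OUT.ATTRS = FALSE)
  E <- apply(grid, 1L, energy_fn)
  w <- exp(-beta * (E - min(E)))
  w <- w / sum(w)
  colSums(grid * w)
}

# First-principles telophase energy on the 3-node tree (root 0,
# children 1 and 2), written as a literal sum over the four rules.
telo_energy_3node <- function(ep, p, G, H, a) {
  act <- ifelse(p > a, p, 0)
  e <- 0
  # rule 1: self-maintenance
  e <- e - G * sum(act * ep)
  # rule 2: each child's proteins silence its parent and sibling
  e <- e + G * act[2] * (ep[1] + ep[3])
  e <- e + G * act[3] * (ep[1] + ep[2])
  # rule 3: root's proteins bivalently mark its children
  e <- e + G * act[1] * (abs(ep[2]) + abs(ep[3]))
  # rule 4: methylation of every non-self, non-descendant module
  e <- e + H * act[2] * (ep[1] + ep[3])
  e <- e + H * act[3] * (ep[1] + ep[2])
  e
}

# First-principles interphase energy on the 3-node tree: field term
# plus mutual repression on the three neighbour pairs.
inter_energy_3node <- function(gen, ep_env, F, J, b) {
  -F * sum((ep_env - b) * gen) +
    J * (gen[1] * gen[2] + gen[1] * gen[3] + gen[2] * gen[3])
}

# Trees used in oracle comparisons: 1 node (levels 1) and 3 nodes
# (levels 2); both enumerable (3^1, 3^3 epigenetic configs).
oracle_trees <- function() list(build_hierarchy(1), build_hierarchy(2))

# Moderate random parameter draws in the regime where the Metropolis
# chain mixes (couplings of order 1/beta); at the production couplings
# the chain is intentionally quasi-deterministic. The update budget is
# raised so that the sampler's own standard error stays well inside
# the 0.02 comparison band.
draw_mixing_params <- function() {
  suppressWarnings(model_parameters(
    G = runif(1, 0.2, 2), H = runif(1, 0.2, 2),
    F = runif(1, 0.2, 2), J = runif(1, 0.2, 2),
    a = runif(1, 0, 0.3), b = runif(1, -0.3, 0.4),
    beta = 1, updates_per_phase = 400000L))
}
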