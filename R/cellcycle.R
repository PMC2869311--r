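#' Cell state: paired per-module epigenetic and expression averages
#'
#' A cell's identity is carried by two vectors of converged phase
#' averages: `ep_avg` (`<S^ep>` in `[-1, 1]`) and `gen_avg` (`<S^gen>`
#' in `[0, 1]`). Label sets are derived by thresholding: a module is
#' expressed if `gen_avg > expression_threshold`; its chromatin is open
#' if `ep_avg > openness_threshold`, silenced if
#' `ep_avg < -openness_threshold`, bivalent otherwise (the three
#' epigenetic labels partition the modules).
#'
#' @param ep_avg,gen_avg Numeric vectors, one entry per module.
#' @param params A [model_parameters()] object (thresholds are captured
#'   in the state).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(ep_avg, gen_avg, params) {
  if (length(ep_avg) != length(gen_avg))
    stop("ep_avg and gen_avg must have equal length")
  if (any(ep_avg < -1 - 1e-9 | ep_avg > 1 + 1e-9))
    stop("ep_avg out of [-1, 1]")
  if (any(gen_avg < -1e-9 | gen_avg > 1 + 1e-9))
    stop("gen_avg out of [0, 1]")
  structure(list(ep_avg = as.numeric(ep_avg),
                 gen_avg = as.numeric(gen_avg),
                 theta_gen = params$expression_threshold,
                 theta_ep = params$openness_threshold),
            class = "cell_state")
}

#' Derived label sets of a cell state
#'
#' @param state A [cell_state()].
#' @return Sorted integer vector of 0-based module ids.
#' @export
expressed_set <- function(state) {
  which(state$gen_avg > state$theta_gen) - 1L
}

#' @rdname expressed_set
#' @export
open_set <- function(state) which(state$ep_avg > state$theta_ep) - 1L

#' @rdname expressed_set
#' @export
bivalent_set <- function(state) {
  which(abs(state$ep_avg) <= state$theta_ep) - 1L
}

#' @rdname expressed_set
#' @export
silenced_set <- function(state) {
  which(state$ep_avg < -state$theta_ep) - 1L
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("cell_state (%d modules)\n", length(x$ep_avg)))
  cat("  expressed:", paste(expressed_set(x), collapse = " "), "\n")
  cat("  open:     ", paste(open_set(x), collapse = " "), "\n")
  cat("  bivalent: ", paste(bivalent_set(x), collapse = " "), "\n")
  cat("  silenced: ", paste(silenced_set(x), collapse = " "), "\n")
  invisible(x)
}

#' Equilibrate the epigenetic lattice for one telophase
#'
#' Runs the compiled Metropolis engine under the telophase Hamiltonian
#' with the protein environment (and any cues) held fixed, returning
#' converged per-module `<S^ep>` averages.
#'
#' @inheritParams telophase_fields
#' @param tol Convergence tolerance on the running-average drift
#'   between the 3rd and 4th quarters of the updates (default 0.15,
#'   just above the intrinsic fluctuation scale of field-free sites).
#' @return A `phase_result` (see [run_phase()]).
#' @export
run_telophase <- function(protein_env, topology, params, cues = NULL,
                          lif_absent = FALSE, rule4_range = "distal",
                          tol = 0.15) {
  fl <- telophase_fields(protein_env, topology, params, cues = cues,
                         lif_absent = lif_absent,
                         rule4_range = rule4_range)
  res <- mc_ternary_field(fl$h, fl$c, params$beta,
                          params$updates_per_phase, tol)
  structure(res[c("avg", "updates", "converged", "drift")],
            class = "phase_result")
}

#' Equilibrate the expression lattice for one interphase
#'
#' Runs the compiled Metropolis engine under the interphase Hamiltonian
#' with the epigenetic averages of the preceding telophase held fixed,
#' returning converged per-module `<S^gen>` averages.
#'
#' @param ep_env Numeric vector of per-module `<S^ep>` in `[-1, 1]`.
#' @inheritParams telophase_fields
#' @inheritParams run_telophase
#' @return A `phase_result`.
#' @export
run_interphase <- function(ep_env, topology, params, tol = 0.15) {
  n <- topology$n_nodes
  if (length(ep_env) != n) stop("ep_env must have one entry per module")
  f <- -params$F * (ep_env - params$b)
  res <- mc_ising_modules(f, 0:(n - 1L), n, neighbor_pairs(topology),
                          params$J, params$beta,
                          params$updates_per_phase, tol)
  structure(res[c("avg", "updates", "converged", "drift")],
            class = "phase_result")
}

#' Advance a cell through one full cycle
#'
#' One cell cycle: gene expression first equilibrates under the current
#' epigenome (interphase), then the resulting protein environment
#' rewrites the epigenetic marks of the dividing cell (telophase). The
#' returned state pairs the fresh telophase `ep_avg` with the
#' interphase `gen_avg` that produced it.
#'
#' @param state A [cell_state()].
#' @inheritParams telophase_fields
#' @return A new `cell_state`.
#' @export
run_cycle <- function(state, topology, params, cues = NULL,
                      lif_absent = FALSE, rule4_range = "distal") {
  stopifnot(inherits(state, "cell_state"))
  gen <- run_interphase(state$ep_avg, topology, params)
  ep <- run_telophase(gen$avg, topology, params, cues = cues,
                      lif_absent = lif_absent, rule4_range = rule4_range)
  cell_state(ep$avg, gen$avg, params)
}

#' Canonical initial states
#'
#' `make_terminal_state()` builds a terminally differentiated cell:
#' the given leaf module open (`ep = +1`) and expressed (`gen = 1`),
#' every other module silenced. `make_es_state()` builds the
#' embryonic-stem attractor: root open and expressed, all other modules
#' bivalent and off.
#'
#' @param topology A [build_hierarchy()] object.
#' @param leaf A leaf module id.
#' @param params A [model_parameters()] object.
#' @return A `cell_state`.
#' @export
make_terminal_state <- function(topology, leaf, params) {
  leaf <- .check_node(topology, leaf)
  if (!is_leaf(topology, leaf))
    stop("module ", leaf, " is not a leaf of the hierarchy")
  n <- topology$n_nodes
  ep <- rep(-1, n); ep[leaf + 1L] <- 1
  gen <- rep(0, n); gen[leaf + 1L] <- 1
  cell_state(ep, gen, params)
}

#' @rdname make_terminal_state
#' @export
make_es_state <- function(topology, params) {
  n <- topology$n_nodes
  ep <- rep(0, n); ep[1L] <- 1
  gen <- rep(0, n); gen[1L] <- 1
  cell_state(ep, gen, params)
}
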