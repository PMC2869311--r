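#' Generic Metropolis Monte Carlo equilibration of one lattice
#'
#' Reference engine over an arbitrary energy function: sites are
#' initialized uniformly at random over their value sets, each update
#' picks a site uniformly, proposes one of the alternative values with
#' equal probability, and accepts with probability
#' `min[1, exp(-beta * dE)]`. Averages are accumulated over the second
#' half of the updates (first half burn-in); convergence is declared
#' when the running averages of the 3rd and 4th quarters differ by less
#' than `tol` at every site (default 0.15, just above the
#' intrinsic fluctuation scale of free sites at the default update
#' budget).
#'
#' This pure-R engine accepts any Hamiltonian and is the one to use for
#' small systems and methodological checks; the production phase
#' simulations ([run_telophase()], [run_interphase()]) use compiled
#' equivalents specialised to the two model Hamiltonians.
#'
#' @param energy_fn Function mapping a full configuration (numeric
#'   vector) to a finite energy.
#' @param state_space List of numeric vectors, one per site, each the
#'   set of values the site can take (at least 2 values).
#' @param params A [model_parameters()] object (`beta`,
#'   `updates_per_phase` are used).
#' @param updates Optional override of `params$updates_per_phase`.
#' @param tol Convergence tolerance on the running-average drift.
#' @return An object of class `phase_result`: list with `avg`,
#'   `updates`, `converged`, `drift`.
#' @export
run_phase <- function(energy_fn, state_space, params, updates = NULL,
                      tol = 0.15) {
  n <- length(state_space)
  if (n < 1L) stop("state_space must contain at least one site")
  if (any(vapply(state_space, length, 1L) < 2L))
    stop("every site needs at least two possible values")
  updates <- if (is.null(updates)) params$updates_per_phase else
    as.integer(updates)
  if (updates < 4L) stop("need at least 4 updates")
  beta <- params$beta

  S <- vapply(state_space, function(v) v[sample.int(length(v), 1L)], 0)
  E <- energy_fn(S)
  if (!is.finite(E)) stop("non-finite energy at the initial configuration")

  half <- updates %/% 2L
  q3_end <- half + (updates - half) %/% 2L
  sum3 <- numeric(n); sum4 <- numeric(n)
  n3 <- 0L; n4 <- 0L
  for (t in seq_len(updates)) {
    i <- sample.int(n, 1L)
    alts <- state_space[[i]][state_space[[i]] != S[i]]
    prop <- S
    prop[i] <- alts[sample.int(length(alts), 1L)]
    Ep <- energy_fn(prop)
    if (!is.finite(Ep)) stop("non-finite energy encountered")
    dE <- Ep - E
    if (dE <= 0 || stats::runif(1) < exp(-beta * dE)) {
      S <- prop; E <- Ep
    }
    if (t > half) {
      if (t <= q3_end) { sum3 <- sum3 + S; n3 <- n3 + 1L }
      else { sum4 <- sum4 + S; n4 <- n4 + 1L }
    }
  }
  drift <- max(abs(sum3 / n3 - sum4 / n4))
  structure(list(avg = (sum3 + sum4) / (n3 + n4), updates = updates,
                 converged = drift < tol, drift = drift),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("phase_result: %d sites, %d updates, converged = %s (drift %.4f)\n",
              length(x$avg), x$updates, x$converged, x$drift))
  print(round(x$avg, 3))
  invisible(x)
}
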