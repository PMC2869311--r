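#' Model parameters for the coupled regulatory-network Hamiltonians
#'
#' Houses the coupling constants of the two effective Hamiltonians and
#' the Monte Carlo settings. Defaults are the standard parameter set
#' used for all headline simulations:
#'
#' * `G` — strength with which the protein atmosphere alters histone
#'   marks (rules 1-3), default 25.
#' * `H` — strength of the long-range DNA-methylation constraint
#'   (rule 4), default 40.
#' * `F` — epigenome-to-expression coupling (rule 1'), default 2000.
#' * `J` — mutual repression between nearest-neighbour modules
#'   (rule 2'), default 3000.
#' * `a` — minimal average expression a protein needs before it acts on
#'   the epigenome, in `[0, 1)`, default 0.
#' * `b` — minimal epigenetic availability `<S^ep>` required to favour
#'   expression, default 0.3 (must exceed the typical MC fluctuation of
#'   the averages, ~0.1).
#' * `beta` — inverse temperature, default 1; it sets the scale of
#'   G, H, F, J.
#' * `updates_per_phase` — Metropolis single-site updates per phase,
#'   default 50000 (sufficient for converged averages at the defaults).
#' * `expression_threshold`, `openness_threshold` — thresholds used to
#'   binarize the phase averages into expressed / open / bivalent /
#'   silenced labels, both default 0.5.
#'
#' Qualitative behaviour is preserved inside the validity region
#' `H > G`, `J > F >> H, G`, `0.1 < b < 0.5`, `0 <= a < 0.6`; a warning
#' (not an error) is emitted for parameter sets outside it.
#'
#' @param G,H,F,J Positive coupling constants (dimensionless energies).
#' @param a Protein-activity threshold in `[0, 1)`.
#' @param b Epigenetic-availability threshold in `[-1, 1]`.
#' @param beta Inverse temperature (> 0).
#' @param updates_per_phase Integer >= 4.
#' @param expression_threshold,openness_threshold Label thresholds in
#'   (0, 1).
#' @return An object of class `model_parameters`.
#' @examples
#' p <- model_parameters()        # standard set
#' p$G; p$H
#' @export
model_parameters <- function(G = 25, H = 40, F = 2000, J = 3000,
                             a = 0, b = 0.3, beta = 1,
                             updates_per_phase = 50000L,
                             expression_threshold = 0.5,
                             openness_threshold = 0.5) {
  num1 <- function(x, nm) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
      stop("'", nm, "' must be a single finite number")
    as.numeric(x)
  }
  G <- num1(G, "G"); H <- num1(H, "H"); F <- num1(F, "F"); J <- num1(J, "J")
  a <- num1(a, "a"); b <- num1(b, "b"); beta <- num1(beta, "beta")
  updates_per_phase <- num1(updates_per_phase, "updates_per_phase")
  expression_threshold <- num1(expression_threshold, "expression_threshold")
  openness_threshold <- num1(openness_threshold, "openness_threshold")

  if (G <= 0 || H <= 0 || F <= 0 || J <= 0 || beta <= 0)
    stop("G, H, F, J and beta must all be strictly positive")
  if (a < 0 || a >= 1) stop("'a' must lie in [0, 1)")
  if (b < -1 || b > 1) stop("'b' must lie in [-1, 1]")
  if (updates_per_phase < 4 ||
      updates_per_phase != as.integer(updates_per_phase))
    stop("'updates_per_phase' must be an integer >= 4")
  if (expression_threshold <= 0 || expression_threshold >= 1)
    stop("'expression_threshold' must lie in (0, 1)")
  if (openness_threshold <= 0 || openness_threshold >= 1)
    stop("'openness_threshold' must lie in (0, 1)")

  outside <- character(0)
  if (!(H > G)) outside <- c(outside, "H > G")
  if (!(J > F)) outside <- c(outside, "J > F")
  if (!(F > 10 * max(H, G))) outside <- c(outside, "F >> H, G")
  if (!(b > 0.1 && b < 0.5)) outside <- c(outside, "0.1 < b < 0.5")
  if (!(a >= 0 && a < 0.6)) outside <- c(outside, "0 <= a < 0.6")
  if (length(outside) > 0L) {
    warning("parameters outside the recommended validity region: ",
            paste(outside, collapse = "; "),
            " - qualitative behaviour is not guaranteed", call. = FALSE)
  }

  structure(
    list(G = G, H = H, F = F, J = J, a = a, b = b, beta = beta,
         updates_per_phase = as.integer(updates_per_phase),
         expression_threshold = expression_threshold,
         openness_threshold = openness_threshold),
    class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("model_parameters:\n")
  cat(sprintf("  G = %g, H = %g, F = %g, J = %g\n", x$G, x$H, x$F, x$J))
  cat(sprintf("  a = %g, b = %g, beta = %g\n", x$a, x$b, x$beta))
  cat(sprintf("  updates/phase = %d, thresholds (gen, ep) = (%g, %g)\n",
              x$updates_per_phase, x$expression_threshold,
              x$openness_threshold))
  invisible(x)
}
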