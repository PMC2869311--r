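#' Self-initiated differentiation of the ES state
#'
#' With the ES culture medium absent (`lif_absent` rule variant), the
#' proteins of the root module open the chromatin of its two immediate
#' progeny during telophase; at the next interphase the root and its
#' two children are all epigenetically available but mutually
#' repressive, so exactly one of them wins expression, stochastically.
#' Each of `n` single-cell simulations starts from the ES state, runs
#' cycles until that three-way decision resolves into a single dominant
#' module, and records the outcome: `self_renewal` (root),
#' `left_child` or `right_child`.
#'
#' @param topology A [build_hierarchy()] object with `levels >= 2`.
#' @param params A [model_parameters()] object.
#' @param n Number of single-cell simulations.
#' @param seed Root seed.
#' @param max_cycles Per-cell cycle budget for the decision
#'   (default 10).
#' @return List with `counts` (named integer vector over the three
#'   outcomes plus `undecided`), `outcomes` (character vector, one per
#'   cell) and `decision_cycle` (integer vector).
#' @export
simulate_self_differentiation <- function(topology, params, n,
                                          seed = 1L, max_cycles = 10L) {
  if (topology$levels < 2L)
    stop("self-differentiation needs a hierarchy with at least 2 levels")
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n)
  kids <- children_of(topology, 0L)
  outcomes <- character(n)
  dcycle <- integer(n)
  for (i in seq_len(n)) {
    set.seed(cell_seeds[i])
    state <- make_es_state(topology, params)
    outcomes[i] <- "undecided"; dcycle[i] <- NA_integer_
    for (cyc in seq_len(max_cycles)) {
      opened <- open_set(state)
      state <- run_cycle(state, topology, params, lif_absent = TRUE)
      d <- expressed_set(state)
      # the decision is read at the first interphase that followed a
      # telophase in which the progeny's chromatin had been opened
      if (any(kids %in% opened) && length(d) == 1L) {
        outcomes[i] <- if (d == 0L) "self_renewal"
          else if (d == kids[1L]) "left_child"
          else if (d == kids[2L]) "right_child" else "undecided"
        dcycle[i] <- cyc
        break
      }
    }
  }
  lv <- c("self_renewal", "left_child", "right_child", "undecided")
  list(counts = table(factor(outcomes, levels = lv)),
       outcomes = outcomes, decision_cycle = dcycle)
}

#' Cue-driven (forward-programming) differentiation from the ES state
#'
#' A differentiation cue is a protein signal that favours positive
#' histone marks on the module regulating the desired progeny
#' (rule 1-like action, strength in units of G; see [cue_spec()]). The
#' cue field acts during every telophase until the cell commits, i.e.
#' until a single non-root module dominates expression. Cells still in
#' the ES (progenitor) state at the start of each cycle are counted,
#' giving the progenitor survival curve.
#'
#' @inheritParams simulate_self_differentiation
#' @param cue A [cue_spec()] whose target is a child of the root.
#' @param max_cycles Per-cell cycle budget (default 40).
#' @param lif_absent Logical; whether the ES-medium-absent rule variant
#'   is also active (default FALSE: the cue acts against a self-renewing
#'   background).
#' @return List with `counts` (`cued`, `other`, `uncommitted`),
#'   `commit_cycle` (per-cell cycle of commitment, NA if uncommitted)
#'   and `progenitor_curve` (data frame `cycle`, `n_progenitor`).
#' @export
simulate_cued_differentiation <- function(topology, params, cue, n,
                                          seed = 1L, max_cycles = 40L,
                                          lif_absent = FALSE) {
  stopifnot(inherits(cue, "cue_spec"))
  if (cue$strength < 0) stop("cue strength must be non-negative")
  kids <- children_of(topology, 0L)
  if (!(cue$target %in% kids))
    stop("the cue target must be a child of the root for a one-step cue")
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n)
  commit_cycle <- rep(NA_integer_, n)
  committed_to <- rep(NA_integer_, n)
  alive <- matrix(FALSE, nrow = max_cycles, ncol = n)
  for (i in seq_len(n)) {
    set.seed(cell_seeds[i])
    state <- make_es_state(topology, params)
    for (cyc in seq_len(max_cycles)) {
      alive[cyc, i] <- TRUE       # still a progenitor entering this cycle
      state <- run_cycle(state, topology, params, cues = list(cue),
                         lif_absent = lif_absent)
      d <- expressed_set(state)
      if (length(d) == 1L && d != 0L) {
        commit_cycle[i] <- cyc
        committed_to[i] <- d
        break
      }
    }
  }
  counts <- c(cued = sum(committed_to == cue$target, na.rm = TRUE),
              other = sum(!is.na(committed_to) &
                            committed_to != cue$target),
              uncommitted = sum(is.na(committed_to)))
  list(counts = counts, commit_cycle = commit_cycle,
       committed_to = committed_to,
       progenitor_curve = data.frame(cycle = seq_len(max_cycles),
                                     n_progenitor = rowSums(alive)))
}

#' Fit an exponential decay to a progenitor survival curve
#'
#' Least-squares fit of `log(n_progenitor)` against cycle, excluding
#' the zero-count tail. The decay rate is minus the slope (per cycle);
#' the progenitor lifetime is its reciprocal.
#'
#' @param curve Data frame with columns `cycle` and `n_progenitor`
#'   (from [simulate_cued_differentiation()]).
#' @return List with `rate`, `lifetime`, `r_squared` and the `lm` fit.
#' @export
fit_progenitor_decay <- function(curve) {
  keep <- curve$n_progenitor > 0
  d <- curve[keep, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("too few non-zero points to fit a decay curve")
  fit <- stats::lm(log(n_progenitor) ~ cycle, data = d)
  rate <- -unname(stats::coef(fit)[2L])
  list(rate = rate, lifetime = 1 / rate,
       r_squared = summary(fit)$r.squared, fit = fit)
}
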