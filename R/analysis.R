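#' Four-point temporal correlation of silencing and activation
#'
#' For binarized expression series `S_i(t)` (1 if unit i is expressed
#' at cycle t), the four-point correlation
#' `C(i, j, dt) = < d(S_i(t),1) d(S_i(t+dt),0) d(S_j(t),0) d(S_j(t+dt),1) >`
#' (d the Kronecker delta) is the joint probability that unit i
#' switches off while unit j switches on across a lag of `dt` cycles.
#' Averaged over successfully reprogrammed trajectories it identifies
#' the most likely reprogramming paths: high values for
#' hierarchy-adjacent pairs, low values for unrelated lineages.
#'
#' The average runs over all trajectories and all valid time origins
#' (`C`); `C_conditional` renormalizes by the number of origins at
#' which unit i actually switched off, i.e. the probability that j
#' turned on given that i turned off.
#'
#' @param trajectories Non-empty list of `trajectory` objects (use the
#'   successfully reprogrammed ones for path analysis).
#' @param dt Lag in cycles (>= 1).
#' @param threshold Binarization threshold on `gen_avg` (default 0.5).
#' @return Data frame with columns `i`, `j`, `dt`, `C`,
#'   `C_conditional`, `n_events`, `n_obs` for all ordered pairs
#'   `i != j`; class `correlation_result`.
#' @export
four_point_correlation <- function(trajectories, dt = 1L,
                                   threshold = 0.5) {
  if (length(trajectories) == 0L) stop("empty trajectory set")
  if (dt < 1L) stop("'dt' must be >= 1")
  mats <- lapply(trajectories, function(tr) {
    if (is.null(tr$gen_avg)) stop("trajectory carries no gen_avg record")
    tr$gen_avg > threshold
  })
  nu <- ncol(mats[[1L]])
  if (any(vapply(mats, ncol, 1L) != nu))
    stop("trajectories have differing numbers of units")
  mats <- mats[vapply(mats, nrow, 1L) > dt]
  if (length(mats) == 0L)
    stop("no trajectory is longer than the requested lag")

  num <- matrix(0, nu, nu)    # joint switch counts
  off_i <- numeric(nu)        # i-switch-off counts
  n_obs <- 0L
  for (B in mats) {
    T_ <- nrow(B)
    pre <- B[seq_len(T_ - dt), , drop = FALSE]
    post <- B[(1L + dt):T_, , drop = FALSE]
    ioff <- pre & !post                     # i on at t, off at t+dt
    jon <- !pre & post                      # j off at t, on at t+dt
    num <- num + crossprod(ioff, jon)       # sum_t ioff[t,i]*jon[t,j]
    off_i <- off_i + colSums(ioff)
    n_obs <- n_obs + (T_ - dt)
  }
  idx <- which(row(num) != col(num), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L, dt = dt,
                    C = num[idx] / n_obs,
                    C_conditional = ifelse(off_i[idx[, 1L]] > 0,
                                           num[idx] / off_i[idx[, 1L]],
                                           0),
                    n_events = num[idx], n_obs = n_obs)
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  class(out) <- c("correlation_result", class(out))
  out
}

#' Census of cycle events and trajectory outcomes
#'
#' @param trajectories Non-empty list of `trajectory` objects.
#' @return List with `events` (counts per classification label) and
#'   `outcomes` (counts per terminal outcome).
#' @export
event_census <- function(trajectories) {
  if (length(trajectories) == 0L) stop("empty trajectory set")
  ev <- unlist(lapply(trajectories, function(tr) tr$cycles$event))
  oc <- vapply(trajectories, function(tr) tr$outcome, "")
  list(events = table(factor(ev, levels = c("return",
         "dedifferentiation", "transdifferentiation", "death_arrest",
         "none"))),
       outcomes = table(factor(oc, levels = c("reprogrammed",
         "dead_arrested", "max_cycles_reached"))))
}

#' Parameter-sensitivity scan
#'
#' Re-runs reduced-size experiments over a grid of parameter overrides
#' and reports, per grid point, the reprogramming efficiency and two
#' qualitative flags: whether early stable root (ES-module) expression
#' is observed within the first cycles of reprogramming trajectories
#' (the anomaly expected when the methylation constraint is weak,
#' `H <= G`), and whether the ES and terminal fixed points hold. Points
#' outside the validity region `H > G`, `J > F` are marked.
#'
#' @param grid Data frame whose columns are [model_parameters()]
#'   argument names (e.g. `G`, `H`, `b`); one row per grid point.
#' @param base_params Baseline [model_parameters()].
#' @param topology A [build_hierarchy()] object.
#' @param n_per_point Trajectories per grid point.
#' @param seed Root seed.
#' @param max_cycles Trajectory cycle budget (default 30; a reduced
#'   scan setting).
#' @return Data frame: the grid, plus `efficiency`, `successes`,
#'   `early_stable_root`, `fixed_points_ok`, `in_validity_region`;
#'   class `sensitivity_report`.
#' @export
sensitivity_scan <- function(grid, base_params, topology, n_per_point,
                             seed = 1L, max_cycles = 30L) {
  if (nrow(grid) == 0L) stop("empty grid")
  set.seed(seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  res <- grid
  res$efficiency <- NA_real_
  res$successes <- NA_integer_
  res$early_stable_root <- NA
  res$fixed_points_ok <- NA
  res$in_validity_region <- NA
  for (r in seq_len(nrow(grid))) {
    args <- as.list(base_params)
    args$updates_per_phase <- NULL
    args <- c(args[setdiff(names(args), names(grid))],
              as.list(grid[r, , drop = FALSE]),
              list(updates_per_phase = base_params$updates_per_phase))
    pars <- suppressWarnings(do.call(model_parameters, args))
    res$in_validity_region[r] <- pars$H > pars$G && pars$J > pars$F

    eff <- estimate_efficiency(topology, pars, n = n_per_point,
                               seed = point_seeds[r],
                               max_cycles = max_cycles, keep = "all")
    res$efficiency[r] <- eff$estimate
    res$successes[r] <- eff$successes
    res$early_stable_root[r] <- any(vapply(eff$trajectories,
                                           .has_early_stable_root, TRUE))
    res$fixed_points_ok[r] <- .fixed_points_hold(topology, pars,
                                                 seed = point_seeds[r])
  }
  class(res) <- c("sensitivity_report", class(res))
  res
}

# root expressed in two consecutive recorded cycles among the first
# cycles of a trajectory, without being the trajectory's stable endpoint
.has_early_stable_root <- function(tr, within = 3L) {
  doms <- strsplit(tr$cycles$dominant, ";", fixed = TRUE)
  has_root <- vapply(doms, function(d) "0" %in% d, TRUE)
  upto <- min(length(has_root) - 1L, within)
  if (upto < 1L) return(FALSE)
  any(has_root[seq_len(upto)] & has_root[seq_len(upto) + 1L])
}

# ES and terminal attractors reproduce their own labels over 3 cycles
.fixed_points_hold <- function(topology, params, seed = 1L,
                               n_cycles = 3L) {
  set.seed(seed)
  es <- make_es_state(topology, params)
  for (i in seq_len(n_cycles)) {
    es <- run_cycle(es, topology, params)
    if (!setequal(expressed_set(es), 0L)) return(FALSE)
  }
  leaf <- leaf_nodes(topology)[1L]
  tm <- make_terminal_state(topology, leaf, params)
  for (i in seq_len(n_cycles)) {
    tm <- run_cycle(tm, topology, params)
    if (!setequal(expressed_set(tm), leaf)) return(FALSE)
  }
  TRUE
}
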