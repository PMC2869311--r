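#' Perturbation policy of the reprogramming factors
#'
#' Reprogramming factors are modelled as random de-silencing events:
#' each cycle, `k` units are drawn uniformly without replacement from
#' the currently silenced pool and their chromatin is switched to open
#' (`ep = +1`). In the base model the units are whole modules and
#' `k = 1`; in the multi-gene variant the units are individual genes
#' (typically `k = 12` for 3 genes/module).
#'
#' @param k Number of de-silencing events per cycle (integer >= 1).
#' @param unit `"module"` or `"gene"`.
#' @return An object of class `perturbation_policy`.
#' @export
perturbation_policy <- function(k = 1L, unit = c("module", "gene")) {
  unit <- match.arg(unit)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != as.integer(k))
    stop("'k' must be a single integer >= 1")
  structure(list(k = as.integer(k), unit = unit),
            class = "perturbation_policy")
}

#' Apply one round of de-silencing perturbations to a cell state
#'
#' Chooses `policy$k` modules uniformly without replacement from the
#' silenced set and sets their `ep_avg` to +1 (open chromatin). If the
#' silenced pool is empty the state is returned unchanged with a
#' warning (fewer than `k` silenced modules: all of them are opened).
#'
#' @param state A [cell_state()].
#' @param policy A [perturbation_policy()].
#' @return List with the new `state` and the integer vector `perturbed`
#'   of chosen module ids.
#' @export
perturb <- function(state, policy = perturbation_policy()) {
  pool <- silenced_set(state)
  if (length(pool) == 0L) {
    warning("no silenced modules to perturb; state unchanged",
            call. = FALSE)
    return(list(state = state, perturbed = integer(0)))
  }
  k <- min(policy$k, length(pool))
  chosen <- if (length(pool) == 1L) pool else
    sort(pool[sample.int(length(pool), k)])
  state$ep_avg[chosen + 1L] <- 1
  list(state = state, perturbed = chosen)
}

# Shared event classification on dominant expressed sets.
.classify_sets <- function(d_prev, d_next, topology) {
  if (length(d_next) == 0L) return("death_arrest")
  if (length(d_next) >= 2L) {
    for (i in seq_along(d_next)) {
      for (j in seq_along(d_next)) {
        if (i < j &&
            !(d_next[j] %in% nearest_neighbors(topology, d_next[i])))
          return("death_arrest")
      }
    }
  }
  if (setequal(d_next, d_prev)) return("return")
  if (length(d_prev) == 1L && length(d_next) == 1L) {
    par <- parent_of(topology, d_prev)
    sib <- sibling_of(topology, d_prev)
    if (!is.na(par) && d_next == par) return("dedifferentiation")
    if (!is.na(sib) && d_next == sib) return("transdifferentiation")
  }
  "none"
}

#' Classify the event between two consecutive cycles
#'
#' Compares the dominant expressed sets of two consecutive cell states:
#' `death_arrest` if nothing is expressed or two expressed modules are
#' not hierarchy nearest neighbours (conflicting identities);
#' `return` if the set is unchanged; `dedifferentiation` /
#' `transdifferentiation` if a single dominant module moved to its
#' parent / sibling; `none` for any other (transient, mixed) change.
#'
#' @param prev,next_state Consecutive [cell_state()] objects.
#' @param topology A [build_hierarchy()] object.
#' @return A single character label.
#' @export
classify_cycle <- function(prev, next_state, topology) {
  .classify_sets(expressed_set(prev), expressed_set(next_state),
                 topology)
}

.is_death_set <- function(d, topology) {
  .classify_sets(integer(0), d, topology) == "death_arrest" ||
    length(d) == 0L
}

#' Simulate one single-cell reprogramming trajectory
#'
#' Starts from a terminally differentiated leaf state and iterates the
#' reprogramming cycle: de-silence random module(s), run interphase
#' then telophase, classify the event. The trajectory stops
#' `reprogrammed` when the dominant expressed set is exactly the root
#' module and one additional perturbation-free confirmation cycle
#' preserves it (stable activation of the endogenous ES module, which
#' in experiments suppresses the exogenous factors); it stops
#' `dead_arrested` when a death/arrest classification persists through
#' one further perturbation-free cycle (single-cycle conflicts are
#' legitimate transients); otherwise it runs to `max_cycles_reached`.
#'
#' @param topology A [build_hierarchy()] object.
#' @param params A [model_parameters()] object.
#' @param policy A [perturbation_policy()].
#' @param start_leaf Leaf module to start from (default: first leaf).
#' @param max_cycles Cycle budget (default 200).
#' @param seed Optional integer seed for this trajectory.
#' @param rule4_range Passed to [telophase_fields()].
#' @return An object of class `trajectory`: list with `start_leaf`,
#'   `cycles` (data frame: cycle, perturbed, event, dominant),
#'   `gen_avg` and `ep_avg` matrices (cycles x modules), `outcome`
#'   (`reprogrammed`, `dead_arrested` or `max_cycles_reached`),
#'   `cycles_used` and `seed`.
#' @export
simulate_trajectory <- function(topology, params,
                                policy = perturbation_policy(),
                                start_leaf = NULL, max_cycles = 200L,
                                seed = NULL, rule4_range = "distal") {
  if (!is.null(seed)) set.seed(seed)
  if (max_cycles < 1L) stop("'max_cycles' must be >= 1")
  if (is.null(start_leaf)) start_leaf <- leaf_nodes(topology)[1L]
  state <- make_terminal_state(topology, start_leaf, params)

  n <- topology$n_nodes
  rec_pert <- character(0); rec_event <- character(0)
  rec_dom <- character(0)
  gen_mat <- NULL; ep_mat <- NULL
  outcome <- "max_cycles_reached"

  record <- function(pert, event, st) {
    rec_pert <<- c(rec_pert, paste(pert, collapse = ";"))
    rec_event <<- c(rec_event, event)
    rec_dom <<- c(rec_dom, paste(expressed_set(st), collapse = ";"))
    gen_mat <<- rbind(gen_mat, st$gen_avg)
    ep_mat <<- rbind(ep_mat, st$ep_avg)
  }

  if (setequal(expressed_set(state), 0L)) {
    # degenerate start: already at the ES/root identity
    return(structure(list(start_leaf = start_leaf,
                          cycles = data.frame(cycle = integer(0),
                                              perturbed = character(0),
                                              event = character(0),
                                              dominant = character(0),
                                              stringsAsFactors = FALSE),
                          gen_avg = matrix(numeric(0), ncol = n),
                          ep_avg = matrix(numeric(0), ncol = n),
                          outcome = "reprogrammed", cycles_used = 0L,
                          seed = seed),
                     class = "trajectory"))
  }

  cyc <- 0L
  while (cyc < max_cycles) {
    cyc <- cyc + 1L
    pb <- suppressWarnings(perturb(state, policy))
    new <- run_cycle(pb$state, topology, params,
                     rule4_range = rule4_range)
    ev <- classify_cycle(state, new, topology)
    record(pb$perturbed, ev, new)
    d_new <- expressed_set(new)

    if (setequal(d_new, 0L) || ev == "death_arrest") {
      if (cyc >= max_cycles) { state <- new; break }
      cyc <- cyc + 1L
      conf <- run_cycle(new, topology, params,
                        rule4_range = rule4_range)
      ev2 <- classify_cycle(new, conf, topology)
      record(integer(0), ev2, conf)
      d_conf <- expressed_set(conf)
      if (setequal(d_new, 0L) && setequal(d_conf, 0L)) {
        outcome <- "reprogrammed"; state <- conf; break
      }
      if (ev == "death_arrest" && .is_death_set(d_conf, topology)) {
        outcome <- "dead_arrested"; state <- conf; break
      }
      state <- conf
    } else {
      state <- new
    }
  }

  structure(list(start_leaf = start_leaf,
                 cycles = data.frame(cycle = seq_along(rec_event),
                                     perturbed = rec_pert,
                                     event = rec_event,
                                     dominant = rec_dom,
                                     stringsAsFactors = FALSE),
                 gen_avg = gen_mat, ep_avg = ep_mat,
                 outcome = outcome, cycles_used = length(rec_event),
                 seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: start leaf %d, %d cycles, outcome %s\n",
              x$start_leaf, x$cycles_used, x$outcome))
  invisible(x)
}

#' Estimate reprogramming efficiency over replicate trajectories
#'
#' Runs `n` independent seeded single-cell trajectories and reports the
#' fraction that reach the stable ES state, with an exact (binomial)
#' 95% confidence interval and the per-outcome counts.
#'
#' @inheritParams simulate_trajectory
#' @param n Number of replicate trajectories (>= 1).
#' @param seed Root seed; per-trajectory seeds are derived from it so
#'   each trajectory is reproducible in isolation.
#' @param keep `"none"`, `"successful"` or `"all"`: which trajectories
#'   to retain in the result.
#' @return An object of class `efficiency_estimate`: list with `n`,
#'   `successes`, `estimate`, `conf_int`, `outcome_counts`,
#'   `trajectories` (possibly empty list), `seed`.
#' @export
estimate_efficiency <- function(topology, params,
                                policy = perturbation_policy(),
                                n, seed = 1L, start_leaf = NULL,
                                max_cycles = 200L,
                                rule4_range = "distal",
                                keep = c("none", "successful", "all")) {
  keep <- match.arg(keep)
  if (n < 1L) stop("'n' must be >= 1")
  set.seed(seed)
  traj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  outcomes <- character(n)
  kept <- list()
  for (i in seq_len(n)) {
    tr <- simulate_trajectory(topology, params, policy,
                              start_leaf = start_leaf,
                              max_cycles = max_cycles,
                              seed = traj_seeds[i],
                              rule4_range = rule4_range)
    outcomes[i] <- tr$outcome
    if (keep == "all" ||
        (keep == "successful" && tr$outcome == "reprogrammed"))
      kept[[length(kept) + 1L]] <- tr
  }
  s <- sum(outcomes == "reprogrammed")
  ci <- stats::binom.test(s, n)$conf.int
  structure(list(n = n, successes = s, estimate = s / n,
                 conf_int = as.numeric(ci),
                 outcome_counts = table(factor(outcomes,
                   levels = c("reprogrammed", "dead_arrested",
                              "max_cycles_reached"))),
                 trajectories = kept, seed = seed),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf(
    "efficiency_estimate: %d/%d reprogrammed (%.3f%%), 95%% CI [%.3f%%, %.3f%%]\n",
    x$successes, x$n, 100 * x$estimate, 100 * x$conf_int[1],
    100 * x$conf_int[2]))
  print(x$outcome_counts)
  invisible(x)
}
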