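#' Expand a module hierarchy into a gene-level topology
#'
#' In the multi-gene variant each master-regulatory module comprises
#' `genes_per_module` individual genes. Genes carry their own epigenetic
#' and expression spins and do not interact directly; modules interact
#' exactly as in the base model, but a module only acts (on the
#' epigenome or through mutual repression) when *all* of its genes are
#' expressed — combinatorial control. Gene `(module m, index g)` maps to
#' lattice site `m * genes_per_module + g` (0-based).
#'
#' @param topology A [build_hierarchy()] object.
#' @param genes_per_module Integer >= 1.
#' @return A `hierarchy_topology` with `genes_per_module` set.
#' @export
expand_topology <- function(topology, genes_per_module) {
  build_hierarchy(topology$levels, genes_per_module)
}

#' Number of gene-level lattice sites
#' @param topology A [build_hierarchy()] object.
#' @return Integer: `n_nodes * genes_per_module`.
#' @export
n_genes <- function(topology) topology$n_nodes * topology$genes_per_module

#' Multi-gene cell state
#'
#' Per-gene epigenetic and expression averages, in module-major order
#' (all genes of module 0, then module 1, ...). A module is *active*
#' only if every one of its genes is expressed above the threshold.
#'
#' @param ep_avg,gen_avg Numeric vectors of length [n_genes()].
#' @param topology A gene-level topology from [expand_topology()].
#' @param params A [model_parameters()] object.
#' @return Object of class `multigene_state` (also `cell_state`).
#' @export
multigene_state <- function(ep_avg, gen_avg, topology, params) {
  ng <- n_genes(topology)
  if (length(ep_avg) != ng || length(gen_avg) != ng)
    stop("state vectors must have one entry per gene")
  st <- cell_state(ep_avg, gen_avg, params)
  st$genes_per_module <- topology$genes_per_module
  st$n_modules <- topology$n_nodes
  class(st) <- c("multigene_state", class(st))
  st
}

#' Module-level views of a multi-gene state
#'
#' `module_activity()` returns, per module, the minimum average
#' expression over its genes (the module acts only through its weakest
#' gene); `active_modules()` the ids of modules whose genes are all
#' expressed above the threshold — the multi-gene analogue of the
#' dominant expressed set.
#'
#' @param state A [multigene_state()].
#' @return Numeric vector / sorted integer vector of module ids.
#' @export
module_activity <- function(state) {
  m <- matrix(state$gen_avg, nrow = state$genes_per_module)
  apply(m, 2L, min)
}

#' @rdname module_activity
#' @export
active_modules <- function(state) {
  which(module_activity(state) > state$theta_gen) - 1L
}

#' Terminally differentiated multi-gene state
#'
#' All genes of the given leaf module open and expressed; every other
#' gene silenced and off.
#'
#' @inheritParams make_terminal_state
#' @export
make_multigene_terminal_state <- function(topology, leaf, params) {
  leaf <- .check_node(topology, leaf)
  if (!is_leaf(topology, leaf)) stop("module ", leaf, " is not a leaf")
  g <- topology$genes_per_module
  ng <- n_genes(topology)
  ep <- rep(-1, ng); gen <- rep(0, ng)
  idx <- leaf * g + seq_len(g)
  ep[idx] <- 1; gen[idx] <- 1
  multigene_state(ep, gen, topology, params)
}

#' Advance a multi-gene cell through one full cycle
#'
#' Interphase: every gene feels its own rule 1' field from its
#' epigenetic average; the rule 2' mutual-repression penalty acts
#' between the *products* of neighbouring modules' gene spins (paid
#' only when two neighbouring modules are simultaneously fully
#' expressed). Telophase: module activities (minimum gene expression,
#' thresholded at `a`) generate exactly the base-model fields, applied
#' identically to every gene of each target module.
#'
#' @param state A [multigene_state()].
#' @inheritParams run_cycle
#' @return A new `multigene_state`.
#' @export
multigene_cycle <- function(state, topology, params,
                            rule4_range = "distal") {
  g <- topology$genes_per_module
  n <- topology$n_nodes
  # interphase on the gene lattice
  f <- -params$F * (state$ep_avg - params$b)
  res_g <- mc_ising_modules(f, rep(0:(n - 1L), each = g), n,
                            neighbor_pairs(topology), params$J,
                            params$beta, params$updates_per_phase)
  gen_avg <- res_g$avg
  # telophase: module-level protein environment, fields per module,
  # replicated to genes
  act <- apply(matrix(gen_avg, nrow = g), 2L, min)
  fl <- telophase_fields(act, topology, params,
                         rule4_range = rule4_range)
  res_e <- mc_ternary_field(rep(fl$h, each = g), rep(fl$c, each = g),
                            params$beta, params$updates_per_phase)
  multigene_state(res_e$avg, gen_avg, topology, params)
}

#' Simulate one multi-gene reprogramming trajectory
#'
#' As [simulate_trajectory()], but perturbations de-silence `k`
#' individual genes per cycle (uniformly without replacement from all
#' genes with silenced chromatin) and events are classified on the
#' module-level active sets.
#'
#' @inheritParams simulate_trajectory
#' @param k Genes de-silenced per telophase.
#' @return A `trajectory` object whose `gen_avg`/`ep_avg` matrices are
#'   gene-level and whose `dominant` column lists active modules.
#' @export
simulate_multigene_trajectory <- function(topology, params, k = 12L,
                                          start_leaf = NULL,
                                          max_cycles = 200L,
                                          seed = NULL,
                                          rule4_range = "distal") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_leaf)) start_leaf <- leaf_nodes(topology)[1L]
  state <- make_multigene_terminal_state(topology, start_leaf, params)
  ng <- n_genes(topology)

  rec_pert <- character(0); rec_event <- character(0)
  rec_dom <- character(0)
  gen_mat <- NULL; ep_mat <- NULL
  outcome <- "max_cycles_reached"

  record <- function(pert, event, st) {
    rec_pert <<- c(rec_pert, paste(pert, collapse = ";"))
    rec_event <<- c(rec_event, event)
    rec_dom <<- c(rec_dom, paste(active_modules(st), collapse = ";"))
    gen_mat <<- rbind(gen_mat, st$gen_avg)
    ep_mat <<- rbind(ep_mat, st$ep_avg)
  }

  perturb_genes <- function(st) {
    pool <- which(st$ep_avg < -st$theta_ep) - 1L   # 0-based gene ids
    if (length(pool) == 0L) return(list(state = st, perturbed = integer(0)))
    kk <- min(k, length(pool))
    chosen <- if (length(pool) == 1L) pool else
      sort(pool[sample.int(length(pool), kk)])
    st$ep_avg[chosen + 1L] <- 1
    list(state = st, perturbed = chosen)
  }

  cyc <- 0L
  while (cyc < max_cycles) {
    cyc <- cyc + 1L
    pb <- perturb_genes(state)
    new <- multigene_cycle(pb$state, topology, params,
                           rule4_range = rule4_range)
    ev <- .classify_sets(active_modules(state), active_modules(new),
                         topology)
    record(pb$perturbed, ev, new)
    d_new <- active_modules(new)

    if (setequal(d_new, 0L) || ev == "death_arrest") {
      if (cyc >= max_cycles) { state <- new; break }
      cyc <- cyc + 1L
      conf <- multigene_cycle(new, topology, params,
                              rule4_range = rule4_range)
      ev2 <- .classify_sets(d_new, active_modules(conf), topology)
      record(integer(0), ev2, conf)
      d_conf <- active_modules(conf)
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
                 seed = seed, genes_per_module = topology$genes_per_module),
            class = "trajectory")
}

#' Estimate multi-gene reprogramming efficiency
#'
#' Runs `n` independent multi-gene trajectories with `k` gene-level
#' de-silencing events per cycle and returns an efficiency estimate
#' with exact binomial confidence interval, as [estimate_efficiency()].
#'
#' @inheritParams simulate_multigene_trajectory
#' @inheritParams estimate_efficiency
#' @export
simulate_multigene_reprogramming <- function(topology, params, k = 12L,
                                             n, seed = 1L,
                                             start_leaf = NULL,
                                             max_cycles = 200L,
                                             keep = c("none",
                                                      "successful",
                                                      "all")) {
  keep <- match.arg(keep)
  if (n < 1L) stop("'n' must be >= 1")
  set.seed(seed)
  traj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  outcomes <- character(n)
  kept <- list()
  for (i in seq_len(n)) {
    tr <- simulate_multigene_trajectory(topology, params, k = k,
                                        start_leaf = start_leaf,
                                        max_cycles = max_cycles,
                                        seed = traj_seeds[i])
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
                 trajectories = kept, seed = seed, k = k),
            class = "efficiency_estimate")
}
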