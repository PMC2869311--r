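#' Load a run configuration from a flat key-value file
#'
#' The config format is plain text, one `key = value` per line, `#`
#' comments, with dotted section prefixes: `run.*` (experiment, levels,
#' genes_per_module, n_trajectories, max_cycles, seed, out_dir,
#' input_tsv, dt, lif_absent, rule4_range, cue_target, cue_strength),
#' `params.*` (any [model_parameters()] argument) and `policy.*`
#' (`k`, `unit`). Omitted parameter keys take the standard defaults.
#' Unknown keys are an error; parameter values outside the validity
#' region warn but do not fail.
#'
#' @param path Path to the config file.
#' @return A validated list of class `run_config` with elements
#'   `experiment`, `levels`, `genes_per_module`, `params`, `policy`,
#'   `n_trajectories`, `max_cycles`, `seed`, `out_dir` and the
#'   experiment-specific extras.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$",
                                  lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad) > 0L)
    stop("unparseable config line(s): ", paste(bad, collapse = " | "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  names(vals) <- keys

  run_keys <- c("experiment", "levels", "genes_per_module",
                "n_trajectories", "max_cycles", "seed", "out_dir",
                "input_tsv", "dt", "lif_absent", "rule4_range",
                "cue_target", "cue_strength", "start_leaf")
  param_keys <- names(formals(model_parameters))
  policy_keys <- c("k", "unit")
  known <- c(paste0("run.", run_keys), paste0("params.", param_keys),
             paste0("policy.", policy_keys))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  pick <- function(key, default = NULL) {
    if (key %in% keys) unname(vals[key]) else default
  }
  as_num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  as_int <- function(x) if (is.null(x)) NULL else as.integer(x)
  as_lgl <- function(x) if (is.null(x)) NULL else
    tolower(x) %in% c("true", "1", "yes")

  par_args <- list()
  for (pk in param_keys) {
    v <- pick(paste0("params.", pk))
    if (!is.null(v)) par_args[[pk]] <- as.numeric(v)
  }
  params <- do.call(model_parameters, par_args)

  experiments <- c("reprogram", "self-differentiate",
                   "cued-differentiate", "multigene-reprogram",
                   "correlation", "sensitivity")
  experiment <- pick("run.experiment", "reprogram")
  if (!experiment %in% experiments)
    stop("run.experiment must be one of: ",
         paste(experiments, collapse = ", "))

  seed <- as_int(pick("run.seed"))
  if (is.null(seed) || is.na(seed))
    stop("run.seed is mandatory for reproducibility")

  cfg <- list(
    experiment = experiment,
    levels = as_int(pick("run.levels", "4")),
    genes_per_module = as_int(pick("run.genes_per_module", "1")),
    params = params,
    policy = perturbation_policy(
      k = as_int(pick("policy.k", "1")),
      unit = pick("policy.unit",
                  if (as_int(pick("run.genes_per_module", "1")) > 1L)
                    "gene" else "module")),
    n_trajectories = as_int(pick("run.n_trajectories", "1000")),
    max_cycles = as_int(pick("run.max_cycles", "200")),
    seed = seed,
    out_dir = pick("run.out_dir", "."),
    input_tsv = pick("run.input_tsv"),
    dt = as_int(pick("run.dt", "1")),
    lif_absent = as_lgl(pick("run.lif_absent", "false")),
    rule4_range = pick("run.rule4_range", "distal"),
    cue_target = as_int(pick("run.cue_target")),
    cue_strength = as_num(pick("run.cue_strength", "2")),
    start_leaf = as_int(pick("run.start_leaf")))
  if (cfg$levels < 1L) stop("run.levels must be >= 1")
  if (cfg$n_trajectories < 1L) stop("run.n_trajectories must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

.fmt9 <- function(x) formatC(x, format = "g", digits = 9)

#' Write a set of trajectories to a TSV log
#'
#' One row per recorded cycle: `run_id`, `cycle`, `phase`,
#' `perturbed_ids` (semicolon list), the per-unit `ep_avg_*` and
#' `gen_avg_*` columns (9 significant digits), `event` and the
#' trajectory `outcome`. The format round-trips through
#' [read_trajectory_tsv()].
#'
#' @param trajectories List of `trajectory` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectories, path) {
  stopifnot(length(trajectories) > 0L)
  nu <- ncol(trajectories[[1L]]$gen_avg)
  header <- c("run_id", "cycle", "phase", "perturbed_ids",
              paste0("ep_avg_", 0:(nu - 1L)),
              paste0("gen_avg_", 0:(nu - 1L)), "event", "outcome")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  for (id in seq_along(trajectories)) {
    tr <- trajectories[[id]]
    if (tr$cycles_used == 0L) next
    for (r in seq_len(nrow(tr$cycles))) {
      row <- c(id, tr$cycles$cycle[r], "cycle",
               tr$cycles$perturbed[r],
               .fmt9(tr$ep_avg[r, ]), .fmt9(tr$gen_avg[r, ]),
               tr$cycles$event[r], tr$outcome)
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a trajectory TSV log back into `trajectory` objects
#'
#' @param path Path written by [write_trajectory_tsv()].
#' @return List of `trajectory` objects (gen/ep matrices, cycle table,
#'   outcome).
#' @export
read_trajectory_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  ep_cols <- grep("^ep_avg_", names(d))
  gen_cols <- grep("^gen_avg_", names(d))
  lapply(split(d, d$run_id), function(dd) {
    dd <- dd[order(dd$cycle), , drop = FALSE]
    structure(list(
      cycles = data.frame(cycle = dd$cycle,
                          perturbed = as.character(dd$perturbed_ids),
                          event = dd$event,
                          dominant = NA_character_,
                          stringsAsFactors = FALSE),
      gen_avg = as.matrix(dd[, gen_cols, drop = FALSE]),
      ep_avg = as.matrix(dd[, ep_cols, drop = FALSE]),
      outcome = dd$outcome[1L], cycles_used = nrow(dd)),
      class = "trajectory")
  })
}

#' Run one configured experiment and write its artifacts
#'
#' Dispatches on `config$experiment` and writes, under
#' `config$out_dir`: a trajectory log TSV (where trajectories are
#' produced), a `summary.json` (config echo, outcome counts,
#' efficiency with CI, wall time, package version, seed) and a plain
#' `run.log`. Identical configs produce byte-identical TSVs.
#'
#' @param config A [load_config()] object (or a list built the same
#'   way).
#' @return Invisibly, a list with the computed result object and the
#'   paths written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) {
    ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out)
  }
  probe <- file.path(out, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("output directory is not writable: ", out)
  unlink(probe)

  t0 <- proc.time()[["elapsed"]]
  logf <- file.path(out, "run.log")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  logmsg <- function(...) writeLines(paste0(...), logcon)
  logmsg("experiment = ", config$experiment, ", seed = ", config$seed)

  topo <- build_hierarchy(config$levels, config$genes_per_module)
  paths <- list(log = logf)
  result <- NULL
  summary_extra <- list()

  if (config$experiment == "reprogram") {
    set.seed(config$seed)
    traj_seeds <- sample.int(.Machine$integer.max - 1L,
                             config$n_trajectories)
    trajs <- vector("list", config$n_trajectories)
    for (i in seq_len(config$n_trajectories)) {
      trajs[[i]] <- simulate_trajectory(
        topo, config$params, config$policy,
        start_leaf = config$start_leaf,
        max_cycles = config$max_cycles, seed = traj_seeds[i],
        rule4_range = config$rule4_range)
      if (i %% 1000L == 0L)
        logmsg("completed ", i, "/", config$n_trajectories,
               " trajectories")
    }
    oc <- vapply(trajs, function(tr) tr$outcome, "")
    s <- sum(oc == "reprogrammed")
    ci <- stats::binom.test(s, length(oc))$conf.int
    paths$tsv <- file.path(out, "trajectories.tsv")
    write_trajectory_tsv(trajs, paths$tsv)
    result <- list(outcome_counts = table(oc), successes = s,
                   efficiency = s / length(oc),
                   conf_int = as.numeric(ci))
    summary_extra <- list(outcome_counts = as.list(table(oc)),
                          efficiency = s / length(oc),
                          conf_int = as.numeric(ci))
  } else if (config$experiment == "multigene-reprogram") {
    eff <- simulate_multigene_reprogramming(
      topo, config$params, k = config$policy$k,
      n = config$n_trajectories, seed = config$seed,
      start_leaf = config$start_leaf, max_cycles = config$max_cycles,
      keep = "all")
    paths$tsv <- file.path(out, "trajectories.tsv")
    write_trajectory_tsv(eff$trajectories, paths$tsv)
    result <- eff
    summary_extra <- list(outcome_counts = as.list(eff$outcome_counts),
                          efficiency = eff$estimate,
                          conf_int = eff$conf_int)
  } else if (config$experiment == "self-differentiate") {
    result <- simulate_self_differentiation(
      topo, config$params, n = config$n_trajectories,
      seed = config$seed)
    summary_extra <- list(outcome_counts = as.list(result$counts))
  } else if (config$experiment == "cued-differentiate") {
    target <- if (is.null(config$cue_target) || is.na(config$cue_target))
      children_of(topo, 0L)[1L] else config$cue_target
    result <- simulate_cued_differentiation(
      topo, config$params,
      cue_spec(target, config$cue_strength),
      n = config$n_trajectories, seed = config$seed,
      lif_absent = isTRUE(config$lif_absent))
    paths$decay_tsv <- file.path(out, "progenitor_decay.tsv")
    utils::write.table(result$progenitor_curve, paths$decay_tsv,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary_extra <- list(outcome_counts = as.list(result$counts))
  } else if (config$experiment == "correlation") {
    if (is.null(config$input_tsv))
      stop("correlation experiment needs run.input_tsv")
    trajs <- read_trajectory_tsv(config$input_tsv)
    trajs <- trajs[vapply(trajs, function(tr)
      tr$outcome == "reprogrammed", TRUE)]
    if (length(trajs) == 0L)
      stop("no successfully reprogrammed trajectories in input")
    result <- four_point_correlation(trajs, dt = config$dt,
                                     threshold =
                                       config$params$expression_threshold)
    paths$tsv <- file.path(out, "correlation.tsv")
    cr <- result
    cr$C <- .fmt9(cr$C); cr$C_conditional <- .fmt9(cr$C_conditional)
    utils::write.table(cr, paths$tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    summary_extra <- list(n_trajectories = length(trajs))
  } else if (config$experiment == "sensitivity") {
    grid <- expand.grid(G = config$params$G,
                        H = c(config$params$G / 2, config$params$H),
                        b = c(0.05, config$params$b))
    result <- sensitivity_scan(grid, config$params, topo,
                               n_per_point = config$n_trajectories,
                               seed = config$seed)
    paths$json <- file.path(out, "sensitivity.json")
    jsonlite::write_json(result, paths$json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }

  wall <- proc.time()[["elapsed"]] - t0
  paths$summary <- file.path(out, "summary.json")
  cfg_echo <- config
  cfg_echo$params <- unclass(config$params)
  cfg_echo$policy <- unclass(config$policy)
  jsonlite::write_json(
    c(list(config = unclass(cfg_echo),
           wall_time_s = round(wall, 3),
           package_version = as.character(
             utils::packageVersion("epihier")),
           seed = config$seed),
      summary_extra),
    paths$summary, auto_unbox = TRUE, digits = NA, null = "null")
  logmsg(sprintf("done in %.1f s", wall))
  invisible(list(result = result, paths = paths))
}

#' Generate small deterministic fixture runs
#'
#' Miniature seeded runs used by the test suite and for hand
#' inspection: `l2-selfdiff` (30 one-decision differentiation outcomes
#' on the 2-level tree), `corr-toy` (a hand-checkable single-switch
#' trajectory for the correlation function) and `terminal-l3` (the
#' 3-level terminal state snapshot as TSV).
#'
#' @param seed Integer seed.
#' @param dir Output directory (default: a session temp dir).
#' @return List with the fixture objects and file paths.
#' @export
generate_fixtures <- function(seed = 1L, dir = tempdir()) {
  params <- model_parameters()
  topo2 <- build_hierarchy(2)
  sd <- simulate_self_differentiation(topo2, params, n = 30L,
                                      seed = seed)

  # two-cycle trajectory with one i->off, j->on switch at the same step
  corr_toy <- structure(list(
    start_leaf = 1L,
    cycles = data.frame(cycle = 1:2, perturbed = c("", ""),
                        event = c("none", "dedifferentiation"),
                        dominant = c("1", "0"),
                        stringsAsFactors = FALSE),
    gen_avg = rbind(c(0, 1, 0), c(1, 0, 0)),
    ep_avg = rbind(c(-1, 1, -1), c(1, 0, -1)),
    outcome = "reprogrammed", cycles_used = 2L, seed = seed),
    class = "trajectory")

  topo3 <- build_hierarchy(3)
  term3 <- make_terminal_state(topo3, leaf_nodes(topo3)[1L], params)

  paths <- list(
    corr_toy = file.path(dir, "corr-toy.tsv"),
    terminal_l3 = file.path(dir, "terminal-l3.tsv"))
  write_trajectory_tsv(list(corr_toy), paths$corr_toy)
  utils::write.table(
    data.frame(module = seq_along(term3$ep_avg) - 1L,
               ep_avg = term3$ep_avg, gen_avg = term3$gen_avg),
    paths$terminal_l3, sep = "\t", row.names = FALSE, quote = FALSE)

  list(l2_selfdiff = sd, corr_toy = corr_toy, terminal_l3 = term3,
       paths = paths)
}
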