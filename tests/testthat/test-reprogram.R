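test_that("perturbation opens uniformly chosen silenced modules", {
  pars <- model_parameters()
  topo <- build_hierarchy(4)
  st <- make_terminal_state(topo, leaf_nodes(topo)[1], pars)
  set.seed(31)
  pb <- perturb(st)
  expect_length(pb$perturbed, 1L)
  expect_true(pb$perturbed %in% silenced_set(st))
  expect_length(silenced_set(pb$state), 13L)   # 14 -> 13
  expect_equal(pb$state$ep_avg[pb$perturbed + 1], 1)

  # empty pool: unchanged, with a warning
  pars1 <- model_parameters()
  es <- make_es_state(build_hierarchy(2), pars1)
  expect_warning(pb0 <- perturb(es), "no silenced")
  expect_length(pb0$perturbed, 0L)
  expect_equal(pb0$state$ep_avg, es$ep_avg)
})

test_that("perturbation choice is uniform over the silenced pool", {
  pars <- model_parameters()
  topo <- build_hierarchy(4)
  st <- make_terminal_state(topo, leaf_nodes(topo)[1], pars)
  pool <- silenced_set(st)
  set.seed(32)
  draws <- replicate(7000, perturb(st)$perturbed)
  counts <- table(factor(draws, levels = pool))
  expect_length(counts, 14L)
  # each ~500; 4 sigma band for multinomial counts
  sd14 <- sqrt(7000 * (1 / 14) * (13 / 14))
  expect_true(all(abs(counts - 500) < 4 * sd14))
})

test_that("cycle classification follows the outcome taxonomy", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  mk <- function(expressed) {
    g <- rep(0, 7); g[expressed + 1] <- 1
    cell_state(rep(0, 7), g, pars)
  }
  leaf <- 3L
  expect_equal(classify_cycle(mk(leaf), mk(1L), topo),
               "dedifferentiation")                 # to the parent
  expect_equal(classify_cycle(mk(leaf), mk(4L), topo),
               "transdifferentiation")              # to the sibling
  expect_equal(classify_cycle(mk(leaf), mk(leaf), topo), "return")
  expect_equal(classify_cycle(mk(leaf), mk(integer(0)), topo),
               "death_arrest")                      # nothing expressed
  expect_equal(classify_cycle(mk(leaf), mk(c(2L, 3L)), topo),
               "death_arrest")                      # conflicting, non-NN
  expect_equal(classify_cycle(mk(leaf), mk(c(1L, 3L)), topo),
               "none")                              # NN pair: transient
  expect_equal(classify_cycle(mk(leaf), mk(5L), topo), "none")
})

test_that("a trajectory started at the ES-like root is immediately
           reprogrammed", {
  pars <- model_parameters()
  topo <- build_hierarchy(1)
  tr <- simulate_trajectory(topo, pars, seed = 5)
  expect_equal(tr$outcome, "reprogrammed")
  expect_equal(tr$cycles_used, 0L)
})

test_that("trajectories terminate with consistent bookkeeping", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  set.seed(40)
  seeds <- sample.int(1e6, 12)
  for (s in seeds) {
    tr <- simulate_trajectory(topo, pars, seed = s, max_cycles = 60)
    expect_true(tr$outcome %in% c("reprogrammed", "dead_arrested",
                                  "max_cycles_reached"))
    expect_equal(nrow(tr$cycles), tr$cycles_used)
    expect_equal(nrow(tr$gen_avg), tr$cycles_used)
    expect_true(all(tr$cycles$event %in% c("return",
      "dedifferentiation", "transdifferentiation", "death_arrest",
      "none")))
    if (tr$outcome == "reprogrammed") {
      last_dom <- tr$cycles$dominant[tr$cycles_used]
      expect_equal(last_dom, "0")    # final dominant set is the root
    }
  }
})

test_that("trajectories are reproducible from their seed", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  t1 <- simulate_trajectory(topo, pars, seed = 99, max_cycles = 40)
  t2 <- simulate_trajectory(topo, pars, seed = 99, max_cycles = 40)
  expect_equal(t1$cycles, t2$cycles)
  expect_equal(t1$gen_avg, t2$gen_avg)
  expect_equal(t1$outcome, t2$outcome)
})

test_that("efficiency estimates carry exact binomial intervals", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  eff <- estimate_efficiency(topo, pars, n = 30, seed = 3,
                             max_cycles = 60, keep = "all")
  expect_equal(sum(eff$outcome_counts), 30)
  expect_length(eff$trajectories, 30L)
  expect_true(eff$conf_int[1] <= eff$estimate &&
                eff$estimate <= eff$conf_int[2])
  # n = 1 degenerate: estimate in {0, 1}
  e1 <- estimate_efficiency(topo, pars, n = 1, seed = 4,
                            max_cycles = 40)
  expect_true(e1$estimate %in% c(0, 1))
  expect_error(estimate_efficiency(topo, pars, n = 0, seed = 1), "n")
})

test_that("successful trajectories move the dominant module only to
           parents or siblings", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  eff <- estimate_efficiency(topo, pars, n = 150, seed = 61,
                             keep = "successful")
  # path locality: every dominant-singleton change is a NN step
  for (tr in eff$trajectories) {
    doms <- strsplit(tr$cycles$dominant, ";", fixed = TRUE)
    singletons <- doms[lengths(doms) == 1]
    path <- as.integer(unlist(singletons))
    steps <- path[-1][path[-1] != path[-length(path)]]
    prev <- path[-length(path)][path[-1] != path[-length(path)]]
    for (k in seq_along(steps)) {
      expect_true(steps[k] %in% c(parent_of(topo, prev[k]),
                                  sibling_of(topo, prev[k])),
                  label = sprintf("step %d -> %d", prev[k], steps[k]))
    }
  }
})
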