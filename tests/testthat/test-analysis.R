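mk_traj <- function(gen_mat, outcome = "reprogrammed") {
  structure(list(cycles = data.frame(
    cycle = seq_len(nrow(gen_mat)),
    perturbed = "", event = "none",
    dominant = apply(gen_mat > 0.5, 1, function(r)
      paste(which(r) - 1L, collapse = ";")),
    stringsAsFactors = FALSE),
    gen_avg = gen_mat, ep_avg = gen_mat * 0,
    outcome = outcome, cycles_used = nrow(gen_mat)),
    class = "trajectory")
}

test_that("four-point correlation vanishes without switching and picks
           up a single coincident switch", {
  # constant trajectories: no events, C = 0 everywhere
  const <- mk_traj(rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)))
  res <- four_point_correlation(list(const), dt = 1)
  expect_true(all(res$C == 0))
  expect_true(all(res$n_events == 0))

  # single two-step trajectory: module 0 switches off while module 1
  # switches on; with series length T the average over the T-1 origins
  # gives C = 1/(T-1)
  sw <- mk_traj(rbind(c(1, 0, 0), c(0, 1, 0)))
  res2 <- four_point_correlation(list(sw), dt = 1)
  expect_equal(res2$C[res2$i == 0 & res2$j == 1], 1)      # T = 2
  expect_equal(res2$C_conditional[res2$i == 0 & res2$j == 1], 1)
  expect_equal(res2$C[res2$i == 1 & res2$j == 0], 0)

  sw3 <- mk_traj(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  res3 <- four_point_correlation(list(sw3), dt = 1)
  expect_equal(res3$C[res3$i == 0 & res3$j == 1], 1 / 2)  # T = 3
  expect_equal(res3$C_conditional[res3$i == 0 & res3$j == 1], 1)
})

test_that("correlation is invariant under trajectory relabelling and
           ignores too-short trajectories", {
  set.seed(81)
  trajs <- lapply(1:4, function(i)
    mk_traj(matrix(rbinom(15, 1, 0.5), ncol = 3)))
  a <- four_point_correlation(trajs, dt = 1)
  b <- four_point_correlation(rev(trajs), dt = 1)
  expect_equal(a$C, b$C)
  # a trajectory shorter than the lag is excluded, not an error
  short <- mk_traj(matrix(c(1, 0, 0), nrow = 1))
  with_short <- four_point_correlation(c(trajs, list(short)), dt = 1)
  expect_equal(with_short$C, a$C)
  expect_error(four_point_correlation(list(short), dt = 1), "lag")
  expect_error(four_point_correlation(list(), dt = 1), "empty")
})

test_that("on successful reprogramming runs the correlation is
           concentrated on hierarchy-adjacent pairs", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  eff <- estimate_efficiency(topo, pars, n = 250, seed = 82,
                             keep = "successful")
  succ <- eff$trajectories
  expect_gt(length(succ), 1)
  res <- four_point_correlation(succ, dt = 1)
  # silencing of the start leaf (3): activation must go to its parent
  # (1) or sibling (4), not to the unrelated lineage (2, 5, 6)
  from3 <- res[res$i == 3, ]
  adj <- sum(from3$C[from3$j %in% c(1, 4)])
  unrel <- sum(from3$C[from3$j %in% c(2, 5, 6)])
  expect_gt(adj, unrel)
})

test_that("event census tallies events and outcomes consistently", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  eff <- estimate_efficiency(topo, pars, n = 40, seed = 83,
                             keep = "all")
  cen <- event_census(eff$trajectories)
  expect_equal(sum(cen$outcomes), 40)
  expect_equal(sum(cen$events),
               sum(vapply(eff$trajectories, function(tr)
                 nrow(tr$cycles), 1L)))
  # most cells die or arrest at the defaults
  expect_gt(cen$outcomes[["dead_arrested"]],
            cen$outcomes[["reprogrammed"]])
  # every successful trajectory needs at least L - 1 = 2 de-/trans-
  # differentiation steps to climb the tree
  for (tr in eff$trajectories) {
    if (tr$outcome != "reprogrammed") next
    steps <- sum(tr$cycles$event %in% c("dedifferentiation",
                                        "transdifferentiation"))
    expect_gte(steps, 2L)
  }
})

test_that("sensitivity scan flags the weak-methylation anomaly", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  grid <- data.frame(H = c(40, 12))    # H > G vs H < G
  rep_ <- sensitivity_scan(grid, pars, topo, n_per_point = 25,
                           seed = 84, max_cycles = 15)
  expect_equal(rep_$in_validity_region, c(TRUE, FALSE))
  expect_false(rep_$early_stable_root[1])
  expect_true(all(c("efficiency", "fixed_points_ok") %in% names(rep_)))
  expect_true(rep_$fixed_points_ok[1])
})
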