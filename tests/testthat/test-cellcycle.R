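test_that("cell state labels partition the modules", {
  pars <- model_parameters()
  st <- cell_state(c(0.9, 0.1, -0.8, 0.4), c(1, 0, 0, 0.6), pars)
  expect_equal(expressed_set(st), c(0L, 3L))
  expect_equal(open_set(st), 0L)
  expect_equal(bivalent_set(st), c(1L, 3L))
  expect_equal(silenced_set(st), 2L)
  labs <- c(open_set(st), bivalent_set(st), silenced_set(st))
  expect_setequal(labs, 0:3)
  expect_length(labs, 4L)
  expect_error(cell_state(c(2, 0), c(0, 0), pars), "ep_avg")
})

test_that("telophase drives the expected chromatin pattern from one
           expressed module", {
  pars <- model_parameters()
  set.seed(21)
  # root expressed on the 2-level tree: children driven to bivalence
  topo2 <- build_hierarchy(2)
  ep <- run_telophase(c(1, 0, 0), topo2, pars)$avg
  expect_gt(ep[1], 0.9)
  expect_true(all(abs(ep[2:3]) < 0.2))
  # a leaf expressed on the 3-level tree: every distal module silenced
  topo3 <- build_hierarchy(3)
  env <- rep(0, 7); env[4] <- 1      # leaf module 3
  ep3 <- run_telophase(env, topo3, pars)$avg
  expect_gt(ep3[4], 0.9)
  expect_true(all(ep3[distal_set(topo3, 3) + 1] < -0.9))
  # no proteins: free ternary sites, averages near 0
  ep0 <- run_telophase(rep(0, 7), topo3, pars)$avg
  expect_true(all(abs(ep0) < 0.2))
})

test_that("interphase expresses exactly the epigenetically available
           modules", {
  pars <- model_parameters()
  set.seed(22)
  topo <- build_hierarchy(2)
  # one open module among silenced ones
  g <- run_interphase(c(1, -1, -1), topo, pars)$avg
  expect_gt(g[1], 0.95)
  expect_true(all(g[2:3] < 0.05))
  # fully silenced: nothing expressed
  g0 <- run_interphase(c(-1, -1, -1), topo, pars)$avg
  expect_true(all(g0 < 0.05))
})

test_that("two open siblings express exactly one module, at about even
           odds across seeds", {
  pars <- model_parameters()
  topo <- build_hierarchy(2)
  set.seed(23)
  winners <- integer(0)
  for (r in 1:60) {
    g <- run_interphase(c(-1, 1, 1), topo, pars)$avg
    d <- which(g > 0.5) - 1L
    expect_length(d, 1L)                       # exactly one expressed
    expect_equal(sum(g[2:3]), 1, tolerance = 0.05)
    winners <- c(winners, d)
  }
  frac <- mean(winners == 1L)
  expect_gt(frac, 0.3)       # ~1/2 within binomial noise at n = 60
  expect_lt(frac, 0.7)
})

test_that("ES and terminal states are fixed points of the cycle", {
  pars <- model_parameters()
  topo <- build_hierarchy(3)
  set.seed(24)
  es <- make_es_state(topo, pars)
  for (i in 1:5) {
    es <- run_cycle(es, topo, pars)
    expect_equal(expressed_set(es), 0L)
    expect_equal(open_set(es), 0L)
    expect_setequal(bivalent_set(es), 1:6)
  }
  leaf <- leaf_nodes(topo)[2]
  tm <- make_terminal_state(topo, leaf, pars)
  for (i in 1:5) {
    tm <- run_cycle(tm, topo, pars)
    expect_equal(expressed_set(tm), leaf)
    expect_equal(open_set(tm), leaf)
    expect_setequal(silenced_set(tm), setdiff(0:6, leaf))
  }
})

test_that("an empty expression pattern stays empty through a cycle", {
  pars <- model_parameters()
  topo <- build_hierarchy(2)
  set.seed(25)
  st <- cell_state(rep(0, 3), rep(0, 3), pars)
  nxt <- run_cycle(st, topo, pars)
  expect_length(expressed_set(nxt), 0L)   # <S^ep> ~ 0 < b blocks all
  expect_true(all(abs(nxt$ep_avg) < 0.2))
})

test_that("terminal state construction validates leaves and counts
           silenced modules", {
  pars <- model_parameters()
  topo4 <- build_hierarchy(4)
  st <- make_terminal_state(topo4, leaf_nodes(topo4)[1], pars)
  expect_length(silenced_set(st), 14L)
  expect_length(open_set(st), 1L)
  expect_error(make_terminal_state(topo4, 0, pars), "leaf")
  topo3 <- build_hierarchy(3)
  st3 <- make_terminal_state(topo3, 3, pars)
  expect_setequal(silenced_set(st3), c(0L, 1L, 2L, 4L, 5L, 6L))
  # degenerate single-module tree: root is the leaf, nothing silenced
  topo1 <- build_hierarchy(1)
  st1 <- make_terminal_state(topo1, 0, pars)
  expect_length(silenced_set(st1), 0L)
})
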