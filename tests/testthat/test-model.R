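test_that("parameter validation enforces positivity and ranges", {
  p <- model_parameters()
  expect_equal(c(p$G, p$H, p$F, p$J, p$a, p$b, p$beta),
               c(25, 40, 2000, 3000, 0, 0.3, 1))
  expect_equal(p$updates_per_phase, 50000L)
  expect_error(model_parameters(J = -1), "positive")
  expect_error(model_parameters(G = 0), "positive")
  expect_error(model_parameters(a = 1.2), "a")
  expect_warning(model_parameters(H = 10), "H > G")
  expect_warning(model_parameters(b = 0.05), "b")
})

test_that("protein activity thresholds at a", {
  expect_equal(protein_activity(0.9, model_parameters(a = 0)), 0.9)
  expect_equal(protein_activity(0.3, suppressWarnings(
    model_parameters(a = 0.5))), 0)
  expect_equal(protein_activity(0, model_parameters()), 0)
  expect_equal(protein_activity(c(0.2, 0.8), suppressWarnings(
    model_parameters(a = 0.5))), c(0, 0.8))
})

test_that("telophase energy matches hand evaluation and zero cases", {
  topo <- build_hierarchy(2)
  pars <- model_parameters()
  # no proteins -> zero energy for every configuration
  cfgs <- expand.grid(e0 = -1:1, e1 = -1:1, e2 = -1:1)
  for (r in seq_len(nrow(cfgs))) {
    expect_equal(telophase_energy(as.numeric(cfgs[r, ]), c(0, 0, 0),
                                  topo, pars), 0)
  }
  # hand-evaluated: left leaf expressed, ep = (root -1, left +1,
  # right -1): term1 -25, term2 -50, term3 0, term4 -80
  expect_equal(telophase_energy(c(-1, 1, -1), c(0, 1, 0), topo, pars),
               -155)
  expect_error(telophase_energy(c(-1, 1), c(0, 1, 0), topo, pars),
               "spin per module")
  expect_error(telophase_energy(c(-1, 2, 0), c(0, 1, 0), topo, pars),
               "spins")
})

test_that("telophase energy agrees with a first-principles rule sum", {
  topo <- build_hierarchy(2)
  set.seed(42)
  for (r in 1:25) {
    pars <- suppressWarnings(model_parameters(
      G = runif(1, 1, 50), H = runif(1, 1, 80), a = runif(1, 0, 0.5)))
    ep <- sample(-1:1, 3, replace = TRUE)
    p <- runif(3)
    expect_equal(
      telophase_energy(ep, p, topo, pars),
      telo_energy_3node(ep, p, pars$G, pars$H, pars$a))
  }
})

test_that("telophase energy is invariant under left/right exchange", {
  topo <- build_hierarchy(3)
  swap <- c(0L, 2L, 1L, 5L, 6L, 3L, 4L) + 1L  # mirror permutation
  pars <- model_parameters()
  set.seed(7)
  for (r in 1:20) {
    ep <- sample(-1:1, 7, replace = TRUE)
    p <- runif(7)
    expect_equal(telophase_energy(ep[swap], p[swap], topo, pars),
                 telophase_energy(ep, p, topo, pars))
  }
})

test_that("interphase energy reproduces closed-form field cases", {
  topo <- build_hierarchy(2)
  pars <- model_parameters()
  # fully silenced epigenome: silence is the minimum; a single
  # expression costs F(1+b)
  expect_equal(interphase_energy(c(0, 0, 0), c(-1, -1, -1), topo, pars),
               0)
  expect_equal(interphase_energy(c(1, 0, 0), c(-1, -1, -1), topo, pars),
               2000 * 1.3)
  # one open module: strong negative field
  expect_equal(interphase_energy(c(1, 0, 0), c(1, -1, -1), topo, pars),
               -1400)
  # two open siblings: co-expression penalised by J
  ep <- c(-1, 1, 1)
  expect_equal(interphase_energy(c(0, 1, 1), ep, topo, pars),
               -2800 + 3000)
  expect_equal(interphase_energy(c(0, 1, 0), ep, topo, pars), -1400)
})

test_that("co-expression of mutual repressors never beats the best singleton", {
  # with J > F the minimum over any neighbouring clique has at most
  # one module expressed
  topo <- build_hierarchy(2)
  pars <- model_parameters()
  ep <- c(1, 1, 1)
  singles <- sapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                    interphase_energy, ep_env = ep, topology = topo,
                    params = pars)
  multis <- sapply(list(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)),
                   interphase_energy, ep_env = ep, topology = topo,
                   params = pars)
  expect_true(min(multis) > min(singles))
})

test_that("external cue fields shift the telophase energy additively", {
  topo <- build_hierarchy(2)
  pars <- model_parameters()
  env <- c(1, 0, 0)
  base <- telophase_energy(c(0, 1, 0), env, topo, pars)
  opened <- telophase_energy(c(0, 1, 0), env, topo, pars,
                             cues = list(cue_spec(1, strength = 2)))
  expect_equal(opened, base - 2 * pars$G)
  silenced <- telophase_energy(c(0, 1, 0), env, topo, pars,
                               cues = list(cue_spec(1, strength = 1,
                                                    type = "silence")))
  expect_equal(silenced, base + pars$G)
})
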