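test_that("actual payoffs evaluate the group games correctly", {
  # all defectors: nothing in any pool, nothing paid
  expect_equal(actual_payoffs(rep(0, 5), fix_k(5), r = 3), rep(0, 5))
  # all cooperators on K_N: every game returns r*N*c/N - c = (r - 1) c
  for (r in c(2, 5)) {
    expect_equal(actual_payoffs(rep(1, 6), fix_k(6), r = r), rep(r - 1, 6))
  }
  # single edge, one cooperator, r = 2, c = 1: two identical 2-player games,
  # f_C = 2*1/2 - 1 = 0 and f_D = 2*1/2 = 1
  f <- actual_payoffs(c(1, 0), fix_edge(), r = 2)
  expect_equal(f, c(0, 1))
  # accumulated payoffs are the average times the number of games
  st <- c(1, 0, 1, 0)
  net <- fix_paw()
  expect_equal(
    actual_payoffs(st, net, "accumulated", r = 3),
    actual_payoffs(st, net, "average", r = 3) * (net$degrees + 1)
  )
})

test_that("elementary updates change at most one strategy by the rules", {
  net <- make_star(5)
  cfg <- sim_config(r = 4, delta = 0.02, rule = "db")
  set.seed(77)
  state <- c(1, rep(0, 5))
  for (step in 1:200) {
    nxt <- update_step(state, net, cfg)
    expect_lte(sum(nxt != state), 1L)
    state <- nxt
    if (sum(state) %in% c(0L, net$n_nodes)) break
  }
  # fixation states are absorbing
  for (rule in c("pc", "db", "bd")) {
    cfgr <- sim_config(r = 4, delta = 0.05, rule = rule)
    expect_equal(update_step(rep(0, 6), net, cfgr), rep(0, 6))
    expect_equal(update_step(rep(1, 6), net, cfgr), rep(1, 6))
  }
})

test_that("neutral PC imitation accepts with probability one half", {
  set.seed(13)
  cfg <- sim_config(r = 2, delta = 0, rule = "pc")
  # on the single edge every step proposes the other node's strategy
  flips <- vapply(1:2000, function(q) {
    any(update_step(c(1, 0), fix_edge(), cfg) != c(1, 0))
  }, logical(1))
  expect_lt(abs(mean(flips) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("compiled runs are reproducible and neutrally unbiased", {
  net <- make_star(9)
  cfg <- sim_config(r = 4, delta = 0, rule = "db", n_runs = 30000, seed = 123)
  rho <- run_to_fixation(net, cfg)
  expect_identical(rho, run_to_fixation(net, cfg))
  expect_true(all(rho %in% c(0, 1)))   # the star fixates quickly
  # neutral fixation probability 1/N within 3 sigma
  expect_lt(abs(mean(rho) - 0.1), 3 * sd(rho) / sqrt(length(rho)))
  # different seeds decorrelate
  cfg2 <- sim_config(r = 4, delta = 0, rule = "db", n_runs = 30000, seed = 124)
  expect_false(identical(rho, run_to_fixation(net, cfg2)))
})

test_that("selection shifts cooperation across the threshold on the lattice", {
  net <- make_lattice(5, "von_neumann")   # DB threshold 4.6 at this size
  cfg <- sim_config(r = 2, delta = 0.025, rule = "db", n_runs = 20000, seed = 42)
  sim <- estimate_cooperation(net, c(2, 8), cfg)
  expect_equal(sim$n_runs, c(20000, 20000))
  # far below the threshold defection is favoured, far above cooperation
  z_gap <- (sim$mean_rhoC[2] - sim$mean_rhoC[1]) /
    sqrt(sum(sim$stderr^2))
  expect_gt(z_gap, 3)
  expect_lt(sim$mean_rhoC[1], 1 / 25)
  expect_gt(sim$mean_rhoC[2], 1 / 25)
})

test_that("crossing estimation recovers a known linear crossing", {
  set.seed(404)
  rg <- c(2, 4, 6, 8)
  sim <- data.frame(
    r = rg,
    mean_rhoC = 0.1 + 0.002 * (rg - 5) + rnorm(4, sd = 5e-4),
    stderr = rep(5e-4, 4),
    n_runs = rep(1000, 4)
  )
  est <- estimate_crossing(sim, n_nodes = 10)
  expect_equal(est$crossing, 5, tolerance = 0.5)
  expect_true(est$ci[1] <= 5 && 5 <= est$ci[2])
  expect_gt(est$slope_z, 1.96)
})

test_that("the threshold object can drive a simulation", {
  th <- pgg_critical_r(make_star(5), "db")
  sim <- simulate(th, nsim = 500, seed = 9, r_grid = c(2, 8))
  expect_equal(nrow(sim), 2L)
  expect_true(all(sim$mean_rhoC >= 0 & sim$mean_rhoC <= 1))
})
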