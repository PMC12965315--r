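test_that("upsilon matrix reproduces the literal expansion term by term", {
  for (net in list(fix_paw(), make_star(4), make_erdos_renyi(12, 0.3, seed = 3))) {
    tau <- solve_coalescence_times(net)
    Y <- upsilon_matrix(net, tau)
    expect_equal(Y, literal_upsilon(net, tau), tolerance = 1e-12)
    expect_true(all(diag(Y) == 0))
  }
  # asymmetric on heterogeneous networks
  star <- make_star(4)
  Ys <- upsilon_matrix(star, solve_coalescence_times(star))
  expect_gt(max(abs(Ys - t(Ys))), 1e-6)
})

test_that("PC and DB thresholds equal their walk-weighted ratio forms", {
  for (net in list(fix_paw(), make_ceiling_fan(3), make_erdos_renyi(15, 0.25, seed = 9))) {
    tau <- solve_coalescence_times(net)
    Y <- upsilon_matrix(net, tau)
    P <- step_distribution(net)
    for (rule in c("pc", "db")) {
      n_steps <- if (rule == "pc") 1 else 2
      Pn <- n_step_distribution(P, n_steps)
      ratio <- weighted_tau(net, tau, n_steps) / sum(net$degrees * Pn * Y)
      expect_equal(pgg_critical_r(net, rule)$value, ratio, tolerance = 1e-10)
    }
  }
})

test_that("the star supports cooperation at exactly r = 4 under DB", {
  for (n in c(2:10, 25, 50)) {
    expect_equal(pgg_critical_r(make_star(n), "db")$value, 4, tolerance = 1e-9)
  }
})

test_that("complete graphs never support cooperation in the PGG", {
  for (n in 4:8) {
    for (rule in c("pc", "db", "bd")) {
      th <- pgg_critical_r(fix_k(n), rule)
      expect_identical(th$category, "no_support")
    }
  }
})

test_that("thresholds match the exact Markov-chain computation", {
  th <- pgg_critical_r(fix_path3(), "pc")
  oc <- oracle_critical(fix_path3(), "pc", "pgg")
  expect_equal(th$value, oc$value, tolerance = 1e-6)

  thd <- dg_critical_bc(fix_cycle(6), "db")
  ocd <- oracle_critical(fix_cycle(6), "db", "dg")
  expect_equal(thd$value, ocd$value, tolerance = 1e-6)

  # accumulated payoffs too
  for (rule in c("pc", "db", "bd")) {
    tha <- pgg_critical_r(fix_path4(), rule, "accumulated")
    oca <- oracle_critical(fix_path4(), rule, "pgg", "accumulated")
    expect_equal(tha$value, oca$value, tolerance = 1e-6)
  }
})

test_that("the condition is invariant under node relabelling", {
  set.seed(5)
  for (net in list(fix_cycle(6), make_star(5), fix_paw())) {
    base <- pgg_critical_r(net, "db")$value
    for (rep in 1:3) {
      perm <- sample(net$n_nodes)
      expect_equal(pgg_critical_r(permute_network(net, perm), "db")$value,
                   base, tolerance = 1e-9)
    }
  }
})

test_that("donation game under PC and BD never supports cooperation", {
  nets <- list(fix_path3(), fix_path4(), fix_paw(), fix_cycle(6), make_star(6),
               make_erdos_renyi(8, 0.4, seed = 12))
  for (net in nets) {
    for (rule in c("pc", "bd")) {
      expect_identical(dg_critical_bc(net, rule)$category, "no_support")
    }
  }
})

test_that("threshold categories are a pure function of the value", {
  expect_identical(
    categorize_threshold(c(0.5, 30, 30.0001, 1000, 1000.5, -2, Inf, -Inf, NaN)),
    c("finite_supporting", "finite_supporting", "strict", "strict",
      "no_support", "no_support", "no_support", "no_support", "no_support")
  )
})

test_that("degenerate inputs are rejected", {
  expect_error(pgg_critical_r(fix_edge(), "pc"), "at least 3")
  two_parts <- adj(4, list(c(1, 2), c(3, 4)))
  suppressWarnings(disc <- pgg_network(two_parts))
  expect_error(pgg_critical_r(disc, "db"), "connected")
})

test_that("threshold objects print their inequality direction", {
  out <- capture.output(print(pgg_critical_r(make_star(9), "db")))
  expect_match(out[1], "DB update")
  expect_match(out[2], "cooperation favoured iff r > value")
  out2 <- capture.output(print(dg_critical_bc(make_star(9), "pc")))
  expect_match(out2[2], "never favoured")
})
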