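test_that("deterministic family generators have the stated shapes", {
  # stars: N = n + 1, hub degree n, leaves degree 1
  for (n in c(1, 7, 9)) {
    s <- make_star(n)
    expect_equal(s$n_nodes, n + 1L)
    expect_equal(sort(s$degrees, decreasing = TRUE), c(n, rep(1L, n)))
  }
  # joint stars: m hubs in a clique, n private leaves each
  js <- make_joint_stars(3, 9)
  expect_equal(js$n_nodes, 30L)
  expect_equal(sort(unique(js$degrees)), c(1L, 11L))
  expect_equal(sum(js$degrees == 11L), 3L)
  js2 <- make_joint_stars(2, 1)
  expect_equal(js2$n_nodes, 4L)
  expect_equal(sort(js2$degrees), c(1L, 1L, 2L, 2L))
  # m = 1 reduces to the plain star
  expect_equal(
    pggnet:::canonical_key(make_joint_stars(1, 5)$adjacency),
    pggnet:::canonical_key(make_star(5)$adjacency)
  )
  # ceiling fans: hub degree 2n, paired leaves of degree 2
  expect_equal(
    pggnet:::canonical_key(make_ceiling_fan(1)$adjacency),
    pggnet:::canonical_key(fix_k(3)$adjacency)
  )
  cf <- make_ceiling_fan(9)
  expect_equal(cf$n_nodes, 19L)
  expect_equal(sort(cf$degrees, decreasing = TRUE), c(18L, rep(2L, 18)))
  # two fans: hub sits in 2 of the C(4,2) possible neighbour pairs
  expect_equal(clustering_coefficient(make_ceiling_fan(2)),
               mean(c(1 / 3, 1, 1, 1, 1)))
})

test_that("periodic lattices are regular with the right neighbourhood", {
  vn <- make_lattice(5, "von_neumann")
  expect_equal(vn$n_nodes, 25L)
  expect_true(all(vn$degrees == 4L))
  mo <- make_lattice(5, "moore")
  expect_true(all(mo$degrees == 8L))
  # 3x3 Moore wrap-around connects every pair: the complete graph K9
  expect_equal(make_lattice(3, "moore")$adjacency, fix_k(9)$adjacency)
  # 4x4 von Neumann torus is bipartite (chessboard colouring)
  vn4 <- make_lattice(4, "von_neumann")
  col <- (rep(0:3, each = 4) + rep(0:3, 4)) %% 2
  same <- outer(col, col, "==")
  expect_true(all(vn4$adjacency[same] == 0L))
  expect_error(make_lattice(2, "von_neumann"), "at least 3")
})

test_that("random generators match their sampling models and reproduce", {
  expect_equal(make_erdos_renyi(5, 1, seed = 1)$adjacency, fix_k(5)$adjacency)
  expect_error(make_erdos_renyi(10, 0), "p_edge")
  # empirical mean degree over many seeds tracks p (N - 1)
  degs <- vapply(1:200, function(s) mean(make_erdos_renyi(50, 0.2, seed = s)$degrees),
                 numeric(1))
  # mean degree = 2E/N with E ~ Binomial(C(50,2), 0.2): sd about 0.56,
  # so 3 standard errors over 200 draws is about 0.12
  expect_lt(abs(mean(degs) - 0.2 * 49), 0.12)

  # Watts-Strogatz: p = 0 is the ring lattice with clustering 3(d-1)/(2(2d-1))
  ws0 <- make_watts_strogatz(100, 2, 0)
  expect_true(all(ws0$degrees == 4L))
  expect_equal(clustering_coefficient(ws0), 0.5)
  expect_equal(
    pggnet:::canonical_key(make_watts_strogatz(10, 1, 0)$adjacency),
    pggnet:::canonical_key(fix_cycle(10)$adjacency)
  )
  # rewiring preserves the edge count
  for (p in c(0.2, 0.8)) {
    ws <- make_watts_strogatz(60, 2, p, seed = 42)
    expect_equal(sum(ws$degrees), 60L * 4L)
  }
  expect_error(make_watts_strogatz(9, 4, 0.1), "too large")

  # preferential attachment: exactly m (N - m) edges
  ba <- make_scale_free(100, 2, gamma = 2, seed = 5)
  expect_equal(sum(ba$degrees) / 2, 2 * (100 - 2))
  expect_equal(mean(ba$degrees), 2 * 2 * (1 - 2 / 100))
  # forced attachment: third node joins both isolated initial nodes -> path
  expect_equal(
    pggnet:::canonical_key(make_scale_free(3, 2, seed = 1)$adjacency),
    pggnet:::canonical_key(fix_path3()$adjacency)
  )

  # bit-reproducible given a seed; caller RNG untouched
  set.seed(99)
  before <- .Random.seed
  a1 <- make_erdos_renyi(40, 0.15, seed = 7)$adjacency
  expect_identical(before, .Random.seed)
  expect_identical(a1, make_erdos_renyi(40, 0.15, seed = 7)$adjacency)
  expect_identical(make_watts_strogatz(40, 2, 0.5, seed = 3)$adjacency,
                   make_watts_strogatz(40, 2, 0.5, seed = 3)$adjacency)
  expect_identical(make_scale_free(40, 2, 1.5, seed = 3)$adjacency,
                   make_scale_free(40, 2, 1.5, seed = 3)$adjacency)

  # every generator output is simple, symmetric and connected
  nets <- list(
    make_star(6), make_joint_stars(2, 3), make_ceiling_fan(4),
    make_lattice(4, "moore"), make_erdos_renyi(30, 0.15, seed = 2),
    make_watts_strogatz(30, 2, 0.3, seed = 2), make_scale_free(30, 2, 1, seed = 2)
  )
  for (net in nets) {
    A <- net$adjacency
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0L))
    expect_true(all(A %in% c(0L, 1L)))
    expect_true(is_connected(net))
  }
})

test_that("edge-list files round-trip and reject malformed input", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# toy path", "a b", "b c"), path)
  net <- read_edge_list(path)
  expect_equal(net$n_nodes, 3L)
  expect_equal(pggnet:::canonical_key(net$adjacency),
               pggnet:::canonical_key(fix_path3()$adjacency))

  write_edge_list(make_star(4), path)
  back <- read_edge_list(path)
  expect_equal(pggnet:::canonical_key(back$adjacency),
               pggnet:::canonical_key(make_star(4)$adjacency))

  writeLines("1 1", path)
  expect_error(read_edge_list(path), "self-loop")
  writeLines(c("# only comments"), path)
  expect_error(read_edge_list(path), "empty")
  writeLines(c("a b", "c d"), path)  # two components
  expect_warning(read_edge_list(path), "not connected")

  write_adjacency_csv(make_star(3), path)
  expect_equal(read_adjacency_csv(path)$adjacency, make_star(3)$adjacency)
})

test_that("clustering coefficient matches hand counts", {
  expect_equal(clustering_coefficient(fix_k(4)), 1)
  expect_equal(clustering_coefficient(make_star(5)), 0)
  # ring lattice d = 2: every node closes 3 of its C(4,2) = 6 neighbour pairs
  expect_equal(clustering_coefficient(make_watts_strogatz(50, 2, 0)), 0.5)
})

test_that("network constructor validates its contract", {
  expect_error(pgg_network(matrix(1, 3, 3)), "self-loops")
  bad <- adj(3, list(c(1, 2)))
  bad[1, 3] <- 1L
  expect_error(pgg_network(bad), "symmetric")
  expect_warning(pgg_network(adj(3, list(c(1, 2)))), "isolated")
})
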