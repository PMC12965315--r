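#' Synthetic network families
#'
#' Deterministic constructions used throughout the cooperation analysis.
#'
#' * `make_star(n_leaves)`: one hub connected to `n_leaves` leaves
#'   (`N = n_leaves + 1`; node 1 is the hub).
#' * `make_joint_stars(m_hubs, n_leaves)`: `m_hubs` mutually connected hubs,
#'   each carrying `n_leaves` private leaves (`N = m_hubs * (1 + n_leaves)`);
#'   `m_hubs = 1` reduces to `make_star()`.
#' * `make_ceiling_fan(n_fans)`: a hub plus `n_fans` "fans", each fan a pair
#'   of leaves connected to each other and to the hub (each fan is a
#'   triangle; `N = 2 * n_fans + 1`).
#' * `make_lattice(side, neighborhood)`: periodic `side x side` square
#'   lattice with von Neumann (4 neighbours, group size 5) or Moore
#'   (8 neighbours, group size 9) neighbourhood.
#'
#' @param n_leaves,m_hubs,n_fans,side positive integers.
#' @param neighborhood `"von_neumann"` or `"moore"`.
#' @return A [pgg_network].
#' @examples
#' make_star(9)                      # N = 10, hub degree 9
#' make_joint_stars(3, 9)            # N = 30, hub degree 11
#' make_lattice(5, "von_neumann")    # N = 25, 4-regular torus
#' @export
make_star <- function(n_leaves) {
  n_leaves <- check_count(n_leaves, "n_leaves")
  A <- matrix(0L, n_leaves + 1L, n_leaves + 1L)
  A[1, -1] <- 1L
  A[-1, 1] <- 1L
  pgg_network(A)
}

#' @rdname make_star
#' @export
make_joint_stars <- function(m_hubs, n_leaves) {
  m_hubs <- check_count(m_hubs, "m_hubs")
  n_leaves <- check_count(n_leaves, "n_leaves")
  n <- m_hubs * (1L + n_leaves)
  A <- matrix(0L, n, n)
  if (m_hubs > 1L) {
    A[seq_len(m_hubs), seq_len(m_hubs)] <- 1L
    diag(A) <- 0L
  }
  for (h in seq_len(m_hubs)) {
    leaves <- m_hubs + (h - 1L) * n_leaves + seq_len(n_leaves)
    A[h, leaves] <- 1L
    A[leaves, h] <- 1L
  }
  pgg_network(A)
}

#' @rdname make_star
#' @export
make_ceiling_fan <- function(n_fans) {
  n_fans <- check_count(n_fans, "n_fans")
  n <- 2L * n_fans + 1L
  A <- matrix(0L, n, n)
  A[1, -1] <- 1L
  A[-1, 1] <- 1L
  for (f in seq_len(n_fans)) {
    a <- 2L * f
    b <- 2L * f + 1L
    A[a, b] <- A[b, a] <- 1L
  }
  pgg_network(A)
}

#' @rdname make_star
#' @export
make_lattice <- function(side, neighborhood = c("von_neumann", "moore")) {
  neighborhood <- match.arg(neighborhood)
  side <- check_count(side, "side")
  if (side < 3L) {
    stop("side must be at least 3 to avoid duplicate edges under periodic wrap-around")
  }
  offs <- if (neighborhood == "moore") {
    cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))[-5, , drop = FALSE]
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  n <- side^2
  A <- matrix(0L, n, n)
  id <- function(r, c) (r %% side) * side + (c %% side) + 1L
  for (r in 0:(side - 1L)) {
    for (c in 0:(side - 1L)) {
      u <- id(r, c)
      v <- id(r + offs[, "dr"], c + offs[, "dc"])
      A[u, v] <- 1L
    }
  }
  diag(A) <- 0L
  A <- A | t(A)
  pgg_network(A * 1L)
}

#' Random network generators
#'
#' The three random families used to probe how local structure shapes
#' cooperation, each conditioned on connectivity by rejection sampling
#' (whole-graph resampling, at most `max_tries` attempts):
#'
#' * `make_erdos_renyi(n_nodes, p_edge)`: each of the `N(N-1)/2` pairs is an
#'   edge independently with probability `p_edge`; expected mean degree
#'   `p_edge * (N - 1)`.
#' * `make_watts_strogatz(n_nodes, d_halfwidth, p_rewire)`: start from the
#'   ring lattice where every node is connected to its `d_halfwidth` nearest
#'   neighbours on each side (degree `2d`); each node considers each of its
#'   `d` clockwise original edges once and, with probability `p_rewire`,
#'   replaces the far endpoint by a uniform choice among non-neighbours
#'   (no self-loops or duplicate edges, an edge is never rewired twice).
#'   Total edge count is preserved.
#' * `make_scale_free(n_nodes, m_attach, gamma)`: growth with tunable
#'   preferential attachment. Starting from `m_attach` isolated nodes, each
#'   new node attaches to `m_attach` distinct existing nodes chosen by
#'   sequential weighted draws with weight `k^gamma` (unit weight for
#'   degree-0 nodes); `gamma = 1` is the classic Barabasi-Albert rich-get-
#'   richer regime, `gamma = 0` uniform attachment. The edge count is
#'   exactly `m_attach * (n_nodes - m_attach)`, so the mean degree is
#'   `2m(1 - m/N)`.
#'
#' @param n_nodes number of nodes.
#' @param p_edge,p_rewire probabilities.
#' @param d_halfwidth ring half-width `d` (each node starts with `2d`
#'   neighbours); requires `2 * d_halfwidth < n_nodes - 1`.
#' @param m_attach edges added per new node.
#' @param gamma preferential-attachment exponent.
#' @param seed optional integer; the draw is reproducible given the seed and
#'   the caller's RNG state is untouched.
#' @param max_tries attempts at a connected draw before erroring.
#' @return A connected [pgg_network].
#' @examples
#' net <- make_erdos_renyi(100, 4 / 99, seed = 1)
#' mean(net$degrees)
#' @export
make_erdos_renyi <- function(n_nodes, p_edge, seed = NULL, max_tries = 10000L) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  if (n_nodes < 2L) stop("n_nodes must be at least 2")
  if (!is.numeric(p_edge) || p_edge <= 0 || p_edge > 1) stop("p_edge must be in (0, 1]")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      A <- matrix(0L, n_nodes, n_nodes)
      ut <- upper.tri(A)
      A[ut] <- rbinom(sum(ut), 1L, p_edge)
      A <- A + t(A)
      net <- pgg_network(A, check_connected = FALSE)
      if (all(net$degrees > 0L) && is_connected(net)) return(net)
    }
    stop("no connected Erdos-Renyi draw in ", max_tries, " attempts")
  })
}

#' @rdname make_erdos_renyi
#' @export
make_watts_strogatz <- function(n_nodes, d_halfwidth, p_rewire, seed = NULL,
                                max_tries = 10000L) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  d_halfwidth <- check_count(d_halfwidth, "d_halfwidth")
  if (2L * d_halfwidth >= n_nodes - 1L) stop("d_halfwidth too large for n_nodes")
  if (!is.numeric(p_rewire) || p_rewire < 0 || p_rewire > 1) {
    stop("p_rewire must be in [0, 1]")
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      A <- matrix(0L, n_nodes, n_nodes)
      for (off in seq_len(d_halfwidth)) {
        i <- seq_len(n_nodes)
        j <- ((i - 1L + off) %% n_nodes) + 1L
        A[cbind(i, j)] <- 1L
        A[cbind(j, i)] <- 1L
      }
      # each node visits its d clockwise original edges once
      for (i in seq_len(n_nodes)) {
        for (off in seq_len(d_halfwidth)) {
          if (runif(1) >= p_rewire) next
          j <- ((i - 1L + off) %% n_nodes) + 1L
          candidates <- which(A[i, ] == 0L)
          candidates <- candidates[candidates != i]
          if (!length(candidates)) next
          jnew <- candidates[sample.int(length(candidates), 1L)]
          A[i, j] <- A[j, i] <- 0L
          A[i, jnew] <- A[jnew, i] <- 1L
        }
      }
      net <- pgg_network(A, check_connected = FALSE)
      if (all(net$degrees > 0L) && is_connected(net)) return(net)
    }
    stop("no connected Watts-Strogatz draw in ", max_tries, " attempts")
  })
}

#' @rdname make_erdos_renyi
#' @export
make_scale_free <- function(n_nodes, m_attach, gamma = 1, seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  m_attach <- check_count(m_attach, "m_attach")
  if (n_nodes <= m_attach) stop("n_nodes must exceed m_attach")
  with_seed(seed, {
    A <- matrix(0L, n_nodes, n_nodes)
    deg <- integer(n_nodes)
    for (new in (m_attach + 1L):n_nodes) {
      existing <- seq_len(new - 1L)
      w <- ifelse(deg[existing] > 0L, deg[existing]^gamma, 1)
      targets <- integer(0)
      for (e in seq_len(m_attach)) {
        pool <- setdiff(existing, targets)
        wp <- w[pool]
        pick <- pool[sample.int(length(pool), 1L, prob = wp)]
        targets <- c(targets, pick)
      }
      A[new, targets] <- 1L
      A[targets, new] <- 1L
      deg[targets] <- deg[targets] + 1L
      deg[new] <- m_attach
    }
    pgg_network(A)
  })
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(name, " must be a positive integer")
  }
  as.integer(x)
}
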