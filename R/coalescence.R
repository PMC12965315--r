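#' Random-walk step kernel
#'
#' One-step transition probabilities of the simple random walk on the
#' network, `p_ij = k_ij / k_i`. `n_step_distribution()` returns the n-th
#' matrix power (`n = 0` is the identity).
#'
#' @param network a connected [pgg_network].
#' @param kernel a one-step kernel as returned by `step_distribution()`.
#' @param n non-negative integer number of steps.
#' @return A row-stochastic `N x N` matrix.
#' @examples
#' P <- step_distribution(make_star(3))
#' rowSums(n_step_distribution(P, 5))   # all 1
#' @export
step_distribution <- function(network) {
  network <- as_pgg_network(network)
  network$adjacency / network$degrees
}

#' @rdname step_distribution
#' @export
n_step_distribution <- function(kernel, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    stop("n must be a non-negative integer")
  }
  out <- diag(nrow(kernel))
  P <- kernel
  n <- as.integer(n)
  while (n > 0L) {            # binary exponentiation
    if (n %% 2L == 1L) out <- out %*% P
    P <- P %*% P
    n <- n %/% 2L
  }
  out
}

#' Coalescence times of ancestral random walks
#'
#' Expected meeting time `tau_ij` of two coalescing random walkers started
#' at nodes `i` and `j`, where in each time unit one of the two walkers
#' (each with probability 1/2) takes a uniform step to a neighbour. The
#' times solve, for `i != j`,
#' \deqn{\tau_{ij} = 1 + \frac{1}{2k_i}\sum_{l \in N_i} \tau_{lj}
#'                     + \frac{1}{2k_j}\sum_{l \in N_j} \tau_{il},}
#' with \eqn{\tau_{ii} = 0}. These meeting times are the neutral-drift
#' backbone of every cooperation condition in the package: under weak
#' selection the two-point correlations of the strategy process are
#' determined by how quickly ancestral lineages coalesce.
#'
#' The `N(N-1)/2` pair equations are solved directly for small systems.
#' For large ones the system is first symmetrised exactly (scaling the
#' `(i,j)` equation by `k_i k_j` yields a symmetric positive-definite
#' M-matrix) and solved by Jacobi-preconditioned conjugate gradient.
#'
#' @param network a connected [pgg_network].
#' @param method `"auto"` (default; direct below 3000 pair unknowns),
#'   `"dense"` or `"cg"`.
#' @param tol relative residual tolerance for the iterative solver.
#' @return A symmetric `N x N` matrix of coalescence times, zero diagonal.
#' @examples
#' solve_coalescence_times(make_star(2))  # path on 3 nodes
#' @export
solve_coalescence_times <- function(network, method = c("auto", "dense", "cg"),
                                    tol = 1e-12) {
  network <- as_pgg_network(network)
  stop_unless_connected(network)
  method <- match.arg(method)
  k <- network$degrees
  # symmetrised system: k_i k_j tau_ij - (k_j/2) sum_{l in N_i \ j} tau_lj
  #                                    - (k_i/2) sum_{l in N_j \ i} tau_il = k_i k_j
  solve_pair_system(
    network,
    diag_coef = function(i, j) k[i] * k[j],
    nbr_coef_i = function(i, j) -k[j] / 2,   # entries for pairs (l, j), l in N_i
    nbr_coef_j = function(i, j) -k[i] / 2,
    rhs = function(i, j) k[i] * k[j],
    method = method, tol = tol
  )
}

#' Ancestral meeting times for the birth-death update rule
#'
#' Under BD updating a node `i` is replaced at rate proportional to its
#' "temperature" `T_i = sum_{g in N_i} 1/k_g`, and the incoming strategy is
#' copied from neighbour `g` with probability proportional to `1/k_g`. The
#' ancestral lineages of the neutral BD process therefore perform a
#' different coalescing walk than under PC/DB, with meeting times solving
#' \deqn{(T_i + T_j)\,\tau_{ij} = N + \sum_{g \in N_i \setminus j}
#'   \tau_{gj}/k_g + \sum_{g \in N_j \setminus i} \tau_{ig}/k_g.}
#' These BD-specific times replace the standard coalescence times in the
#' BD cooperation conditions.
#'
#' @inheritParams solve_coalescence_times
#' @return A symmetric `N x N` matrix, zero diagonal.
#' @export
bd_meeting_times <- function(network, method = c("auto", "dense", "cg"),
                             tol = 1e-12) {
  network <- as_pgg_network(network)
  stop_unless_connected(network)
  method <- match.arg(method)
  k <- network$degrees
  n <- network$n_nodes
  Tt <- as.vector(network$adjacency %*% (1 / k))
  # symmetrised by scaling the (i,j) equation with 1/(k_i k_j)
  solve_pair_system(
    network,
    diag_coef = function(i, j) (Tt[i] + Tt[j]) / (k[i] * k[j]),
    nbr_coef_i = function(i, j, l) -1 / (k[i] * k[j] * k[l]),
    nbr_coef_j = function(i, j, l) -1 / (k[i] * k[j] * k[l]),
    rhs = function(i, j) n / (k[i] * k[j]),
    method = method, tol = tol, coef_uses_l = TRUE
  )
}

# Assemble and solve a symmetric linear system over unordered node pairs.
# Row (i, j): diag_coef * x_ij + sum_{l in N_i, l != j} nbr_coef_i * x_lj
#                              + sum_{l in N_j, l != i} nbr_coef_j * x_il = rhs.
solve_pair_system <- function(network, diag_coef, nbr_coef_i, nbr_coef_j, rhs,
                              method = "auto", tol = 1e-12, coef_uses_l = FALSE) {
  A <- network$adjacency
  n <- nrow(A)
  k <- network$degrees
  ut <- which(upper.tri(A), arr.ind = TRUE)
  np <- nrow(ut)
  pidx <- matrix(0L, n, n)
  pidx[ut] <- seq_len(np)
  pidx <- pidx + t(pidx)
  nbr <- adj_list(network)
  iv <- ut[, 1]
  jv <- ut[, 2]

  rep_i <- rep.int(seq_len(np), k[iv])
  li <- unlist(nbr[iv], use.names = FALSE)
  keep <- li != jv[rep_i]
  r1 <- rep_i[keep]
  l1 <- li[keep]
  c1 <- pidx[cbind(l1, jv[r1])]
  v1 <- if (coef_uses_l) nbr_coef_i(iv[r1], jv[r1], l1) else nbr_coef_i(iv[r1], jv[r1])

  rep_j <- rep.int(seq_len(np), k[jv])
  lj <- unlist(nbr[jv], use.names = FALSE)
  keep <- lj != iv[rep_j]
  r2 <- rep_j[keep]
  l2 <- lj[keep]
  c2 <- pidx[cbind(iv[r2], l2)]
  v2 <- if (coef_uses_l) nbr_coef_j(iv[r2], jv[r2], l2) else nbr_coef_j(iv[r2], jv[r2])

  dvals <- diag_coef(iv, jv)
  b <- rhs(iv, jv)

  if (method == "dense" || (method == "auto" && np <= 3000L)) {
    M <- matrix(0, np, np)
    M[cbind(seq_len(np), seq_len(np))] <- dvals
    M[cbind(r1, c1)] <- M[cbind(r1, c1)] + v1
    M[cbind(r2, c2)] <- M[cbind(r2, c2)] + v2
    x <- solve(M, b)
  } else {
    M <- Matrix::sparseMatrix(
      i = c(seq_len(np), r1, r2), j = c(seq_len(np), c1, c2),
      x = c(dvals, v1, v2), dims = c(np, np)
    )
    x <- cg_spd(M, b, tol = tol)
  }
  out <- matrix(0, n, n)
  out[ut] <- x
  out[cbind(jv, iv)] <- x
  out
}

# Jacobi-preconditioned conjugate gradient for sparse SPD systems.
cg_spd <- function(M, b, tol = 1e-12, maxit = 100000L) {
  d <- Matrix::diag(M)
  x <- b / d
  r <- b - as.vector(M %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Mp <- as.vector(M %*% p)
    alpha <- rz / sum(p * Mp)
    x <- x + alpha * p
    r <- r - alpha * Mp
    if (sqrt(sum(r^2)) <= tol * bn) return(x)
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stop("conjugate gradient did not converge")
}

#' Walk-weighted total coalescence time
#'
#' The aggregate \eqn{\tau^{(n)} = \sum_{i,j} k_i\, p^{(n)}_{ij}\, \tau_{ij}}
#' appearing in the cooperation conditions: coalescence times weighted by
#' degree and the n-step random-walk kernel.
#'
#' @param network a connected [pgg_network].
#' @param times coalescence times from [solve_coalescence_times()] for the
#'   same network.
#' @param n number of walk steps (PC conditions use `n = 1`, DB `n = 2`).
#' @return numeric scalar.
#' @export
weighted_tau <- function(network, times, n) {
  network <- as_pgg_network(network)
  check_times(network, times)
  Pn <- n_step_distribution(step_distribution(network), n)
  sum(network$degrees * Pn * times)
}

stop_unless_connected <- function(network) {
  if (any(network$degrees == 0L) || !is_connected(network)) {
    stop("network must be connected")
  }
}

check_times <- function(network, times) {
  if (!is.matrix(times) || nrow(times) != network$n_nodes ||
      ncol(times) != network$n_nodes) {
    stop("times matrix does not match the network")
  }
}
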