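#' Linear payoff coefficients of a game on a network
#'
#' Both games assign each node a payoff that is linear in the binary
#' strategy vector `x`: `f = cost * (factor * B x - D x)`, where `factor`
#' is the synergy factor `r` (public goods game) or the benefit-to-cost
#' ratio `b/c` (donation game). For the PGG with average payoffs,
#' `B = diag(1/G) H diag(1/G) H` with `H = A + I` the closed adjacency and
#' `G = k + 1` the group sizes, and `D = I`: node `i` averages, over the
#' `G_i` games it joins, the public-goods share \eqn{r c \, n_C(G_l) / G_l}
#' minus its own contributed cost. Accumulated payoffs drop the leading
#' `1/G_i` average. The donation game pays `b` per cooperating neighbour
#' (averaged or summed over neighbours) at cost `c` per game played.
#'
#' @param network a [pgg_network].
#' @param game `"pgg"` or `"dg"`.
#' @param payoff_scheme `"average"` or `"accumulated"`.
#' @return list with matrix `B` and diagonal vector `D`.
#' @keywords internal
payoff_coefficients <- function(network, game = c("pgg", "dg"),
                                payoff_scheme = c("average", "accumulated")) {
  game <- match.arg(game)
  payoff_scheme <- match.arg(payoff_scheme)
  A <- network$adjacency
  n <- network$n_nodes
  k <- network$degrees
  if (game == "pgg") {
    G <- k + 1
    H <- A + diag(n)
    B <- (H %*% (H / G)) / G       # (1/G_i) sum_{m in G_i} (1/G_m) [l in G_m]
    D <- rep(1, n)
    if (payoff_scheme == "accumulated") {
      B <- B * G
      D <- G
    }
  } else {
    B <- A / k
    D <- rep(1, n)
    if (payoff_scheme == "accumulated") {
      B <- A
      D <- k
    }
  }
  list(B = B, D = D)
}

#' Payoff-weighted coalescence matrix for the PGG
#'
#' The matrix \eqn{\Upsilon_{ij}} that aggregates coalescence-time
#' differences with the public-goods payoff structure (average payoffs):
#' \deqn{\Upsilon_{ij} = \frac{1}{G_i}\Big\{\frac{1}{G_i}\big[\tau_{ij} +
#'   \sum_{l\in N_i}(\tau_{jl}-\tau_{il})\big] + \sum_{l\in N_i}
#'   \frac{1}{G_l}\big[(\tau_{jl}-\tau_{il}) + \sum_{\ell\in N_l}
#'   (\tau_{j\ell}-\tau_{i\ell})\big]\Big\},}
#' so that cooperation under pairwise comparison is favoured when
#' \eqn{r > \tau^{(1)}/\Upsilon^{(1)}} with
#' \eqn{\Upsilon^{(n)} = \sum_{i,j} k_i p^{(n)}_{ij} \Upsilon_{ij}}.
#' \eqn{\Upsilon_{ii} = 0} because \eqn{\tau_{ii} = 0}, and generally
#' \eqn{\Upsilon_{ij} \neq \Upsilon_{ji}} on heterogeneous networks.
#'
#' Computed as \eqn{\Upsilon_{ij} = (B\tau)_{ij} - (B\tau)_{ii}} with `B`
#' the average-payoff benefit coefficients, which reproduces the expanded
#' sum above term by term.
#'
#' @param network a connected [pgg_network].
#' @param times coalescence times from [solve_coalescence_times()].
#' @return An `N x N` matrix with zero diagonal.
#' @export
upsilon_matrix <- function(network, times) {
  network <- as_pgg_network(network)
  check_times(network, times)
  B <- payoff_coefficients(network, "pgg", "average")$B
  BT <- B %*% times
  Y <- BT - diag(BT)            # column-recycled: Y_ij = (BT)_ij - (BT)_ii
  diag(Y) <- 0
  Y
}

#' Critical synergy factor and critical benefit-to-cost ratio
#'
#' The central computation of the package: the threshold above which weak
#' selection favours the fixation of a single cooperator over the neutral
#' benchmark `1/N`.
#'
#' For an update rule with pair weights `W` and ancestral meeting times
#' `tau`, cooperation is favoured if and only if
#' \deqn{\sum_{i,j,l} W_{ij}\,(a_{il}-a_{jl})\,(\tau_{jl}-\tau_{il}) > 0,}
#' where `a = cost * (factor * B - diag(D))` are the linear payoff
#' coefficients of the game ([payoff_coefficients()]). The pair weights are
#' `k_ij` for pairwise comparison (PC: imitation competes with first
#' neighbours), `k_i p^(2)_ij` for death-birth (DB: competition for a
#' vacancy reaches second neighbours) and `k_ij/(k_i k_j)` for birth-death
#' (BD: global fitness-proportional reproduction into a random neighbour),
#' with BD using its own ancestral meeting times ([bd_meeting_times()]).
#' Solving for the factor gives the threshold as a ratio of a cost sum to
#' a benefit sum; under PC with average payoffs this is exactly
#' `tau(1)/Upsilon(1)` and under DB `tau(2)/Upsilon(2)` (see
#' [weighted_tau()], [upsilon_matrix()]).
#'
#' A positive benefit sum yields a finite threshold and the condition
#' "cooperation favoured iff factor > value". A negative benefit sum flips
#' the inequality (`factor < value < 0`), so cooperation is impossible for
#' meaningful factors; a vanishing benefit sum means the threshold
#' diverges. Values are categorised as `finite_supporting` (0 < value <=
#' 30), `strict` (30 < value <= 1000) or `no_support` (negative or above
#' 1000, the numerical proxy for divergence).
#'
#' @param network a connected [pgg_network] with at least 3 nodes.
#' @param rule update rule: `"pc"`, `"db"` or `"bd"`.
#' @param payoff_scheme `"average"` (default) or `"accumulated"`.
#' @return An object of class `pgg_threshold`: list with `value`,
#'   `category`, `game`, `rule`, `payoff_scheme`, `n_nodes`, the cost and
#'   benefit sums, and the network.
#' @examples
#' pgg_critical_r(make_star(9), "db")            # exactly 4
#' dg_critical_bc(make_lattice(3, "von_neumann"), "db")
#' @seealso [oracle_critical()] for the exact small-network cross-check.
#' @export
pgg_critical_r <- function(network, rule = c("pc", "db", "bd"),
                           payoff_scheme = c("average", "accumulated")) {
  critical_threshold(network, "pgg", match.arg(rule), match.arg(payoff_scheme))
}

#' @rdname pgg_critical_r
#' @export
dg_critical_bc <- function(network, rule = c("pc", "db", "bd"),
                           payoff_scheme = c("average", "accumulated")) {
  critical_threshold(network, "dg", match.arg(rule), match.arg(payoff_scheme))
}

critical_threshold <- function(network, game, rule, payoff_scheme,
                               times = NULL) {
  network <- as_pgg_network(network)
  if (network$n_nodes < 3L) stop("thresholds require at least 3 nodes")
  stop_unless_connected(network)
  if (is.null(times)) {
    times <- if (rule == "bd") bd_meeting_times(network)
             else solve_coalescence_times(network)
  }
  pcf <- payoff_coefficients(network, game, payoff_scheme)
  s <- threshold_sums(network, rule, pcf, times)
  value <- threshold_value(s$benefit, s$cost)
  structure(
    list(
      value = value, category = categorize_threshold(value),
      game = game, rule = rule, payoff_scheme = payoff_scheme,
      n_nodes = network$n_nodes, cost_sum = s$cost, benefit_sum = s$benefit,
      network = network
    ),
    class = "pgg_threshold"
  )
}

# pair weights W and the two aggregate sums of the selection condition
threshold_sums <- function(network, rule, pcf, times) {
  A <- network$adjacency
  k <- network$degrees
  W <- switch(rule,
    pc = A,
    db = A %*% (A / k),                    # k_i p^(2)_ij
    bd = (A / k) / rep(k, each = nrow(A))  # k_ij / (k_i k_j)
  )
  BT <- pcf$B %*% times
  d <- diag(BT)
  benefit <- sum(W * (BT + t(BT) - outer(d, rep(1, length(d))) -
                        outer(rep(1, length(d)), d)))
  cost <- sum(W * (pcf$D + rep(pcf$D, each = length(pcf$D))) * times)
  list(benefit = benefit, cost = cost)
}

threshold_value <- function(benefit, cost) {
  if (abs(benefit) < 1e-12 * abs(cost)) return(Inf)
  cost / benefit
}

#' Categorise a cooperation threshold
#'
#' Pure function of the threshold value: `finite_supporting` for values in
#' `(0, 30]`, `strict` for `(30, 1000]`, and `no_support` for negative,
#' non-finite or above-1000 values (the numerical convention for a
#' divergent threshold).
#'
#' @param value numeric vector of thresholds.
#' @return character vector of categories.
#' @export
categorize_threshold <- function(value) {
  out <- ifelse(
    !is.finite(value) | value < 0 | value > 1000, "no_support",
    ifelse(value <= 30, "finite_supporting", "strict")
  )
  out[is.na(value)] <- "no_support"
  out
}

#' @export
print.pgg_threshold <- function(x, ...) {
  lab <- if (x$game == "pgg") "critical synergy factor r*" else "critical benefit-to-cost (b/c)*"
  cat(sprintf(
    "%s [%s update, %s payoffs, N = %d]\n", lab, toupper(x$rule),
    x$payoff_scheme, x$n_nodes
  ))
  if (x$category == "no_support") {
    cat(sprintf(
      "  value = %s: cooperation is never favoured on this network\n",
      format(x$value, digits = 6)
    ))
  } else {
    cat(sprintf(
      "  value = %s (%s): cooperation favoured iff %s > value\n",
      format(x$value, digits = 8), x$category,
      if (x$game == "pgg") "r" else "b/c"
    ))
  }
  invisible(x)
}

#' @export
summary.pgg_threshold <- function(object, ...) {
  print(object)
  cat(sprintf(
    "  cost sum = %.6g, benefit sum = %.6g\n",
    object$cost_sum, object$benefit_sum
  ))
  invisible(object)
}

#' Simulate the stochastic dynamics behind a threshold
#'
#' Runs the agent-based Monte Carlo simulator on the network stored in a
#' [pgg_critical_r()] result, over a grid of synergy factors around the
#' theoretical threshold, and returns the mean final cooperator fraction
#' per grid point (see [estimate_cooperation()]).
#'
#' @param object a `pgg_threshold` for the public goods game.
#' @param nsim runs per grid point.
#' @param seed optional integer master seed.
#' @param r_grid synergy factors to simulate; defaults to five points
#'   spanning 0.5--1.5 times the threshold value.
#' @param delta selection strength.
#' @param ... passed to [sim_config()].
#' @return A data frame from [estimate_cooperation()].
#' @export
simulate.pgg_threshold <- function(object, nsim = 1000, seed = NULL,
                                   r_grid = NULL, delta = 0.025, ...) {
  if (object$game != "pgg") stop("simulation is available for the public goods game")
  if (object$category == "no_support") {
    if (is.null(r_grid)) r_grid <- c(2, 4, 8, 16)
  } else if (is.null(r_grid)) {
    r_grid <- object$value * c(0.5, 0.75, 1, 1.25, 1.5)
  }
  cfg <- sim_config(
    r = r_grid[1], rule = object$rule, payoff_scheme = object$payoff_scheme,
    n_runs = nsim, delta = delta, seed = seed, ...
  )
  estimate_cooperation(object$network, r_grid, cfg)
}

#' @export
plot.pgg_threshold <- function(x, sim = NULL, ...) {
  if (is.null(sim)) sim <- simulate(x, nsim = 2000)
  plot(sim$r, sim$mean_rhoC, type = "b", pch = 16,
       xlab = if (x$game == "pgg") "synergy factor r" else "b/c",
       ylab = "mean final cooperator fraction", ...)
  abline(h = 1 / x$n_nodes, lty = 3)
  if (x$category != "no_support") abline(v = x$value, lty = 2)
  invisible(x)
}
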