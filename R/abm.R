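#' Simulation configuration
#'
#' Bundles the parameters of an agent-based Monte Carlo run. Defaults
#' follow the standard protocol: cost `c = 1`, numerically weak selection,
#' up to `4e5` full Monte Carlo steps (each MCS is `N` elementary updates,
#' so every agent updates once on average), and a single random cooperator
#' among `N - 1` defectors as the initial state.
#'
#' @param r synergy factor.
#' @param cost contribution cost `c`.
#' @param delta selection strength (0 allowed for neutral checks).
#' @param rule update rule: `"pc"`, `"db"` or `"bd"`.
#' @param payoff_scheme `"average"` or `"accumulated"`.
#' @param max_mcs maximum number of full Monte Carlo steps per run.
#' @param n_runs independent runs.
#' @param seed optional integer master seed; per-run streams are derived
#'   deterministically from `(seed, run index)`.
#' @return An object of class `pgg_sim_config`.
#' @export
sim_config <- function(r, cost = 1, delta = 0.02, rule = c("db", "pc", "bd"),
                       payoff_scheme = c("average", "accumulated"),
                       max_mcs = 4e5, n_runs = 1L, seed = NULL) {
  rule <- match.arg(rule)
  payoff_scheme <- match.arg(payoff_scheme)
  stopifnot(r > 0, cost >= 0, delta >= 0, max_mcs >= 1, n_runs >= 1)
  structure(
    list(r = r, cost = cost, delta = delta, rule = rule,
         payoff_scheme = payoff_scheme, max_mcs = as.integer(max_mcs),
         n_runs = as.integer(n_runs),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "pgg_sim_config"
  )
}

#' Actual payoffs of every agent in a strategy state
#'
#' Each agent plays one public goods game per group it belongs to (its own
#' and each neighbour's). In the game organised by `l`, every member
#' receives \eqn{r c \, n_C(G_l) / G_l} and cooperating
#' members pay `cost`. The actual payoff is the average (or, for the
#' accumulated scheme, the sum) over an agent's `G_i` games.
#'
#' @param state 0/1 integer vector of strategies (1 = cooperate).
#' @param network a [pgg_network].
#' @param payoff_scheme `"average"` or `"accumulated"`.
#' @param r synergy factor.
#' @param cost contribution cost.
#' @return Numeric payoff vector.
#' @examples
#' net <- make_star(3)
#' actual_payoffs(c(1, 0, 0, 0), net, r = 2)
#' @export
actual_payoffs <- function(state, network, payoff_scheme = c("average", "accumulated"),
                           r, cost = 1) {
  payoff_scheme <- match.arg(payoff_scheme)
  network <- as_pgg_network(network)
  stopifnot(length(state) == network$n_nodes, all(state %in% c(0, 1)))
  H <- network$adjacency + diag(network$n_nodes)
  G <- network$degrees + 1
  pool <- as.vector(H %*% state)
  f <- as.vector(H %*% (r * cost * pool / G)) - state * cost * G
  if (payoff_scheme == "average") f <- f / G
  f
}

#' One elementary update step (reference implementation)
#'
#' Performs a single stochastic strategy update in R, for testing and
#' inspection; the production simulator runs the same dynamics compiled.
#' PC: a uniform focal agent imitates a uniform neighbour with the Fermi
#' probability `1 / (1 + exp(-delta * (f_j - f_i)))`. DB: a uniform focal
#' agent dies and adopts the strategy of a neighbour chosen with
#' probability proportional to fitness `exp(delta * f)`. BD: an agent is
#' chosen proportionally to fitness in the whole population and its
#' strategy replaces a uniform neighbour. At most one strategy changes.
#'
#' @param state 0/1 strategy vector.
#' @param network a [pgg_network].
#' @param config a [sim_config()] (uses `r`, `cost`, `delta`, `rule`,
#'   `payoff_scheme`).
#' @return Updated strategy vector.
#' @export
update_step <- function(state, network, config) {
  network <- as_pgg_network(network)
  n <- network$n_nodes
  nbr <- adj_list(network)
  f <- actual_payoffs(state, network, config$payoff_scheme, config$r, config$cost)
  Fw <- exp(config$delta * f)
  if (config$rule == "pc") {
    i <- sample.int(n, 1L)
    j <- nbr[[i]][sample.int(length(nbr[[i]]), 1L)]
    if (runif(1) < 1 / (1 + exp(-config$delta * (f[j] - f[i])))) state[i] <- state[j]
  } else if (config$rule == "db") {
    i <- sample.int(n, 1L)
    js <- nbr[[i]]
    j <- js[sample.int(length(js), 1L, prob = Fw[js])]
    state[i] <- state[j]
  } else {
    j <- sample.int(n, 1L, prob = Fw)
    i <- nbr[[j]][sample.int(length(nbr[[j]]), 1L)]
    state[i] <- state[j]
  }
  state
}

#' Run the stochastic dynamics to fixation
#'
#' Starts from one cooperator at a uniformly random node, performs
#' elementary updates until full cooperation or full defection is reached
#' (early exit) or `max_mcs` Monte Carlo steps elapse, and returns the
#' final cooperator fraction (1, 0, or the truncation-time fraction).
#'
#' @param network a connected [pgg_network].
#' @param config a [sim_config()]; `n_runs` of 1 returns a scalar,
#'   otherwise a vector of final fractions.
#' @return Numeric vector of final cooperator fractions, length `n_runs`.
#' @export
run_to_fixation <- function(network, config) {
  network <- as_pgg_network(network)
  stop_unless_connected(network)
  seed <- if (is.null(config$seed)) {
    as.integer(floor(runif(1) * .Machine$integer.max))
  } else config$seed
  cpp_simulate_runs(
    network$adjacency, rule_code(config$rule),
    config$payoff_scheme == "average", config$r, config$cost, config$delta,
    config$n_runs, config$max_mcs, seed
  )
}

rule_code <- function(rule) match(rule, c("pc", "db", "bd")) - 1L

#' Mean cooperation across a grid of synergy factors
#'
#' Repeats [run_to_fixation()] `n_runs` times per grid value and reports
#' the mean final cooperator fraction with its standard error. Evolution
#' favours cooperation at a given `r` when the mean exceeds the neutral
#' benchmark `1/N`; the empirical crossing of `1/N` estimates the critical
#' synergy factor.
#'
#' @param network a connected [pgg_network].
#' @param r_grid synergy factors to evaluate.
#' @param config a [sim_config()]; per-run random streams are derived from
#'   `config$seed` and the run index, so results are reproducible and
#'   independent of evaluation order.
#' @return Data frame with columns `r`, `mean_rhoC`, `stderr`, `n_runs`.
#' @export
estimate_cooperation <- function(network, r_grid, config) {
  network <- as_pgg_network(network)
  stop_unless_connected(network)
  stopifnot(length(r_grid) >= 1, all(is.finite(r_grid)))
  base_seed <- if (is.null(config$seed)) {
    as.integer(floor(runif(1) * .Machine$integer.max))
  } else config$seed
  out <- lapply(seq_along(r_grid), function(gi) {
    rho <- cpp_simulate_runs(
      network$adjacency, rule_code(config$rule),
      config$payoff_scheme == "average", r_grid[gi], config$cost, config$delta,
      config$n_runs, config$max_mcs, base_seed + 1000003L * (gi - 1L)
    )
    data.frame(
      r = r_grid[gi], mean_rhoC = mean(rho),
      stderr = stats::sd(rho) / sqrt(length(rho)), n_runs = length(rho)
    )
  })
  do.call(rbind, out)
}

#' Locate the cooperation crossing from simulated data
#'
#' Weighted least-squares fit of the mean cooperator fraction against the
#' synergy factor; the crossing of the neutral level `1/N` estimates the
#' critical synergy factor, with a 95% Fieller-type confidence interval.
#' Under weak selection the fixation probability is linear in `r` to first
#' order in the selection strength, so a linear fit is appropriate near
#' the threshold.
#'
#' @param sim data frame from [estimate_cooperation()].
#' @param n_nodes population size (for the neutral level `1/N`).
#' @param level confidence level.
#' @return List with `crossing`, `ci` (may be infinite when the slope is
#'   not significant), `slope`, `slope_z` (slope / its standard error).
#' @export
estimate_crossing <- function(sim, n_nodes, level = 0.95) {
  y <- sim$mean_rhoC - 1 / n_nodes
  # weighted least squares with the simulation standard errors taken as
  # known variances (no residual-dispersion estimate)
  w <- 1 / pmax(sim$stderr, 1e-12)^2
  X <- cbind(1, sim$r)
  V <- solve(crossprod(X, X * w))
  ab <- V %*% crossprod(X, y * w)
  a <- ab[1]
  b <- ab[2]
  z <- qnorm(1 - (1 - level) / 2)
  # Fieller interval for -a/b
  g <- z^2 * V[2, 2] / b^2
  crossing <- -a / b
  if (g < 1) {
    centre <- crossing + g * (crossing + V[1, 2] / V[2, 2]) / (1 - g)
    half <- z / (abs(b) * (1 - g)) *
      sqrt(V[1, 1] + 2 * crossing * V[1, 2] + crossing^2 * V[2, 2] -
             g * (V[1, 1] - V[1, 2]^2 / V[2, 2]))
    ci <- c(centre - half, centre + half)
  } else {
    ci <- c(-Inf, Inf)
  }
  list(crossing = unname(crossing), ci = unname(ci), slope = unname(b),
       slope_z = unname(b / sqrt(V[2, 2])))
}
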