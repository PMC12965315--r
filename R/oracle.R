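#' Exact fixation probability of a single cooperator
#'
#' Brute-force ground truth on small networks: builds the full transition
#' matrix of the strategy-evolution Markov chain over all `2^N` strategy
#' states for the chosen update rule and selection strength, solves the
#' absorbing-chain linear system for the probability of reaching
#' all-cooperation, and averages over the `N` single-cooperator initial
#' states (the initial cooperator is placed uniformly at random). Under
#' neutral selection (`delta = 0`) the result is exactly `1/N` for every
#' rule on every connected network.
#'
#' Payoffs are computed directly from the game definition: in the public
#' goods game each group member receives \eqn{r c \, n_C / G} from each
#' game, cooperators pay `cost` per game, and the
#' per-game payoffs are averaged or summed according to `payoff_scheme`;
#' the donation game pays `value * cost` per cooperating neighbour.
#'
#' @param network a connected [pgg_network] with at most 12 nodes.
#' @param rule `"pc"`, `"db"` or `"bd"`.
#' @param game `"pgg"` or `"dg"`.
#' @param payoff_scheme `"average"` or `"accumulated"`.
#' @param value synergy factor `r` (PGG) or benefit-to-cost ratio (DG).
#' @param delta selection strength (may be 0 or negative; weak selection
#'   analysis uses the derivative at 0).
#' @param cost contribution cost `c`.
#' @return Fixation probability in `[0, 1]`.
#' @examples
#' exact_fixation_probability(make_star(3), "db", value = 4, delta = 0)  # 1/4
#' @export
exact_fixation_probability <- function(network, rule = c("pc", "db", "bd"),
                                       game = c("pgg", "dg"),
                                       payoff_scheme = c("average", "accumulated"),
                                       value, delta, cost = 1) {
  rule <- match.arg(rule)
  game <- match.arg(game)
  payoff_scheme <- match.arg(payoff_scheme)
  network <- as_pgg_network(network)
  stop_unless_connected(network)
  n <- network$n_nodes
  if (n > 12L) stop("exact computation is limited to 12 nodes (2^N states)")
  A <- network$adjacency
  k <- network$degrees
  S <- 2L^n
  states <- matrix(0L, S, n)
  for (i in seq_len(n)) {
    states[, i] <- bitwAnd(bitwShiftR(seq_len(S) - 1L, i - 1L), 1L)
  }
  f <- oracle_payoffs(states, A, k, game, payoff_scheme, value, cost)
  E <- exp(delta * f)                     # fitness, S x n

  # ordered adjacent pairs (i, j): i may copy j's strategy
  ord <- which(A == 1L, arr.ind = TRUE)
  i <- ord[, 1]
  j <- ord[, 2]
  w <- switch(rule,
    pc = E[, j, drop = FALSE] / (E[, i, drop = FALSE] + E[, j, drop = FALSE]) /
      (n * rep(k[i], each = S)),
    db = E[, j, drop = FALSE] / (E %*% t(A))[, i, drop = FALSE] / n,
    bd = E[, j, drop = FALSE] / rowSums(E) / rep(k[j], each = S)
  )
  differ <- states[, i, drop = FALSE] != states[, j, drop = FALSE]
  w <- w * differ
  # target state index when i flips to j's strategy
  flip <- sweep(1L - 2L * states[, i, drop = FALSE], 2L, 2L^(i - 1L), "*")
  target <- (seq_len(S) - 1L) + flip * differ

  Tm <- matrix(0, S, S)
  for (q in seq_along(i)) {
    idx <- cbind(seq_len(S), target[, q] + 1L)
    Tm[idx] <- Tm[idx] + w[, q]
  }
  diag(Tm) <- diag(Tm) + 1 - rowSums(Tm)

  allD <- 1L
  allC <- S
  trans <- setdiff(seq_len(S), c(allD, allC))
  u <- solve(diag(length(trans)) - Tm[trans, trans], Tm[trans, allC])
  ufull <- numeric(S)
  ufull[allC] <- 1
  ufull[trans] <- u
  mean(ufull[1L + 2L^(seq_len(n) - 1L)])
}

# payoff matrix over all states (rows) and nodes (columns), from the game
# definition itself (independent of the coefficient machinery in thresholds)
oracle_payoffs <- function(states, A, k, game, payoff_scheme, value, cost) {
  n <- ncol(states)
  G <- k + 1
  if (game == "pgg") {
    H <- A + diag(n)
    pool <- states %*% H                     # cooperators in group organised by l
    share <- (value * cost) * pool / rep(G, each = nrow(states))
    f <- share %*% H - states * cost * rep(G, each = nrow(states))
    if (payoff_scheme == "average") f <- f / rep(G, each = nrow(states))
  } else {
    f <- (value * cost) * states %*% A - cost * states * rep(k, each = nrow(states))
    if (payoff_scheme == "average") f <- f / rep(k, each = nrow(states))
  }
  f
}

#' Critical threshold from the exact Markov chain
#'
#' The definitive small-network arbiter for the weak-selection theory: the
#' derivative of the fixation probability with respect to the selection
#' strength at `delta = 0` is linear in the game factor (synergy factor or
#' benefit-to-cost ratio). It is estimated by central finite differences
#' at `delta = 1e-4` (with Richardson-style refinement at `5e-5` when the
#' two estimates disagree) for two probe factors, and the root of the
#' resulting linear function is the critical value. A negative or
#' vanishing slope in the factor means the network cannot support
#' cooperation at any meaningful factor.
#'
#' @inheritParams exact_fixation_probability
#' @param probes two factor values at which the derivative is evaluated.
#' @param delta finite-difference step.
#' @return List with `value` (root; `Inf` when the slope vanishes),
#'   `category` (as in [categorize_threshold()], `no_support` for negative
#'   slope), `alpha` and `beta` (intercept and slope of the
#'   delta-derivative as a function of the factor).
#' @examples
#' oracle_critical(make_star(3), "db")$value   # 4
#' @export
oracle_critical <- function(network, rule = c("pc", "db", "bd"),
                            game = c("pgg", "dg"),
                            payoff_scheme = c("average", "accumulated"),
                            probes = c(2, 6), delta = 1e-4, cost = 1) {
  rule <- match.arg(rule)
  game <- match.arg(game)
  payoff_scheme <- match.arg(payoff_scheme)
  slope_at <- function(v) {
    est <- function(d) {
      (exact_fixation_probability(network, rule, game, payoff_scheme, v, d, cost) -
       exact_fixation_probability(network, rule, game, payoff_scheme, v, -d, cost)) / (2 * d)
    }
    s1 <- est(delta)
    s2 <- est(delta / 2)
    if (abs(s1 - s2) > 1e-5 * max(abs(s1), abs(s2), 1e-12)) s2 else s1
  }
  a1 <- slope_at(probes[1])
  a2 <- slope_at(probes[2])
  beta <- (a2 - a1) / (probes[2] - probes[1])
  alpha <- a1 - beta * probes[1]
  scale <- max(abs(a1), abs(a2), 1e-300)
  if (abs(beta) < 1e-9 * max(1, scale)) {
    value <- Inf
    category <- "no_support"
  } else {
    value <- -alpha / beta
    category <- if (beta < 0) "no_support" else categorize_threshold(value)
  }
  list(value = value, category = category, alpha = alpha, beta = beta)
}
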