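#' Infinite-size extrapolation of a threshold sequence
#'
#' Thresholds on the synthetic families converge to their infinite-size
#' limits with leading order `1/n`; fitting `value ~ a + b/n` over a
#' ladder of sizes and reporting the intercept `a` estimates the limit.
#'
#' @param sizes numeric vector of sizes (leaf counts, fan counts, or `N`).
#' @param values thresholds at those sizes.
#' @return List with `limit` (intercept), `slope`, and `max_residual` of
#'   the fit (a large residual signals that `1/n` is not the right order).
#' @export
extrapolate_threshold <- function(sizes, values) {
  stopifnot(length(sizes) == length(values), length(sizes) >= 2)
  fit <- lm(values ~ I(1 / sizes))
  list(limit = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       max_residual = max(abs(stats::resid(fit))))
}

#' Thresholds across the synthetic network families
#'
#' Critical synergy factors for stars, joint stars, ceiling fans and
#' periodic lattices at a ladder of finite sizes, with a `1/n`
#' extrapolation column estimating the infinite-size limit. The classic
#' reference points: stars give 4 under DB at every size; ceiling fans
#' tend to 21/4 (PC) and 27/8 (DB); joint stars with `m` hubs tend to
#' `4m/(2m-1)` (PC) and `(12m-4)/(9m-7)` (DB).
#'
#' @param rules update rules to tabulate.
#' @param payoff_scheme payoff scheme.
#' @param star_sizes,fan_sizes,joint_sizes,lattice_sides size ladders
#'   (leaf counts, fan counts, leaf counts per hub, lattice sides).
#' @param joint_hubs number of hubs `m` for the joint-star family.
#' @return Data frame with one row per family/rule: the size ladder, the
#'   threshold at each size (`value_1`, `value_2`, ...), the extrapolated
#'   limit and the extrapolation fit residual.
#' @export
threshold_family_table <- function(rules = c("pc", "db"),
                                   payoff_scheme = "average",
                                   star_sizes = c(10, 20, 40),
                                   fan_sizes = c(10, 20, 40),
                                   joint_sizes = c(10, 20, 40),
                                   joint_hubs = 3,
                                   lattice_sides = c(6, 8, 10)) {
  fam <- list(
    star = list(sizes = star_sizes,
                build = function(n) make_star(n)),
    joint_stars = list(sizes = joint_sizes,
                       build = function(n) make_joint_stars(joint_hubs, n)),
    ceiling_fan = list(sizes = fan_sizes,
                       build = function(n) make_ceiling_fan(n)),
    lattice_von_neumann = list(sizes = lattice_sides,
                               build = function(n) make_lattice(n, "von_neumann")),
    lattice_moore = list(sizes = lattice_sides,
                         build = function(n) make_lattice(n, "moore"))
  )
  rows <- list()
  for (fname in names(fam)) {
    sizes <- fam[[fname]]$sizes
    nets <- lapply(sizes, fam[[fname]]$build)
    for (rule in rules) {
      vals <- vapply(nets, function(net) {
        pgg_critical_r(net, rule, payoff_scheme)$value
      }, numeric(1))
      # lattices converge in 1/N = 1/side^2
      xs <- if (grepl("lattice", fname)) sizes^2 else sizes
      ex <- extrapolate_threshold(xs, vals)
      row <- data.frame(family = fname, rule = rule,
                        sizes = paste(sizes, collapse = ","), t(vals),
                        limit = ex$limit, fit_residual = ex$max_residual,
                        stringsAsFactors = FALSE)
      names(row)[4:(3 + length(sizes))] <- paste0("value_", seq_along(sizes))
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Mean threshold across random-network ensembles
#'
#' Generates `n_networks` connected random networks per parameter value
#' and averages the critical synergy factor, tracing how average degree
#' (Erdos-Renyi `p`), clustering (Watts-Strogatz rewiring `p`) or degree
#' heterogeneity (preferential-attachment exponent `gamma`) shape
#' cooperation.
#'
#' @param kind `"er"`, `"ws"` or `"ba"`.
#' @param params parameter values (`p_edge`, `p_rewire`, or `gamma`).
#' @param n_nodes network size.
#' @param n_networks draws per parameter value.
#' @param rule update rule.
#' @param payoff_scheme payoff scheme.
#' @param seed master seed; draw `g` of parameter index `q` uses seed
#'   `seed + 1000 * q + g`.
#' @param d_halfwidth,m_attach structural parameters for WS / BA.
#' @return Data frame with `param`, `mean_rstar`, `stderr`,
#'   `mean_clustering`, `n_networks` (non-finite thresholds are excluded
#'   from the mean; column `n_finite` reports how many entered).
#' @export
random_network_sweep <- function(kind = c("er", "ws", "ba"), params,
                                 n_nodes = 100, n_networks = 50,
                                 rule = "db", payoff_scheme = "average",
                                 seed = 1, d_halfwidth = 2, m_attach = 2) {
  kind <- match.arg(kind)
  rows <- lapply(seq_along(params), function(q) {
    vals <- numeric(n_networks)
    cl <- numeric(n_networks)
    for (g in seq_len(n_networks)) {
      s <- seed + 1000L * q + g
      net <- switch(kind,
        er = make_erdos_renyi(n_nodes, params[q], seed = s),
        ws = make_watts_strogatz(n_nodes, d_halfwidth, params[q], seed = s),
        ba = make_scale_free(n_nodes, m_attach, params[q], seed = s)
      )
      vals[g] <- pgg_critical_r(net, rule, payoff_scheme)$value
      cl[g] <- clustering_coefficient(net)
    }
    ok <- is.finite(vals) & vals > 0 & vals <= 1000
    data.frame(
      param = params[q],
      mean_rstar = mean(vals[ok]),
      stderr = stats::sd(vals[ok]) / sqrt(max(sum(ok), 1)),
      mean_clustering = mean(cl),
      n_networks = n_networks, n_finite = sum(ok)
    )
  })
  do.call(rbind, rows)
}

#' Full small-graph census report
#'
#' Enumerates all connected graphs for the requested sizes, computes
#' thresholds for both games under all requested rules, and summarises:
#' census counts, category fractions per game/rule, and (when size 8 is
#' included) the percentile rank of the star and the identity of the worst
#' networks.
#'
#' @param n_range sizes (subset of 3:8).
#' @param rules update rules.
#' @param payoff_scheme payoff scheme.
#' @param progress print progress lines.
#' @return List with `census` (the full table), `counts`, `fractions`
#'   (category fractions per game/rule) and `star_rank` (per rule, when
#'   `max(n_range) >= 4`).
#' @export
census_report <- function(n_range = 3:8, rules = c("pc", "db", "bd"),
                          payoff_scheme = "average", progress = FALSE) {
  census <- census_thresholds(n_range, rules = rules, games = c("pgg", "dg"),
                              payoff_scheme = payoff_scheme, progress = progress)
  counts <- table(census$n)
  combos <- expand.grid(game = c("pgg", "dg"), rule = rules,
                        stringsAsFactors = FALSE)
  fractions <- lapply(seq_len(nrow(combos)), function(ci) {
    classify_census(n_range, combos$game[ci], combos$rule[ci],
                    payoff_scheme, census = census)
  })
  names(fractions) <- paste(combos$game, combos$rule, sep = "_")
  star_rank <- NULL
  nmax <- max(n_range)
  star <- make_star(nmax - 1L)
  star_rank <- vapply(rules, function(rl) {
    rank_percentile(star, "pgg", rl, payoff_scheme, census = census)
  }, numeric(1))
  list(census = census, counts = counts, fractions = fractions,
       star_rank = star_rank)
}
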