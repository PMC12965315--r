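#' Enumerate all connected graphs up to isomorphism
#'
#' Isomorph-free exhaustive generation of connected simple graphs on
#' `n_nodes` nodes by canonical augmentation: every connected graph on `n`
#' nodes arises from a connected graph on `n - 1` nodes by attaching a new
#' node to a non-empty subset of the old nodes (delete any non-cut vertex
#' to see this), so graphs are grown one node at a time and duplicates are
#' pruned with a canonical form (BLISS canonical labelling via igraph).
#' The counts for `n = 3..8` are 2, 6, 21, 112, 853 and 11,117.
#'
#' @param n_nodes integer between 3 and 8.
#' @return A list of 0/1 adjacency matrices, one canonical representative
#'   per isomorphism class, in deterministic order.
#' @examples
#' length(enumerate_connected(5))  # 21
#' @export
enumerate_connected <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 3 || n_nodes > 8 ||
      n_nodes != floor(n_nodes)) {
    stop("n_nodes must be an integer between 3 and 8")
  }
  reps <- list(matrix(0L, 1L, 1L))
  for (n in 2:n_nodes) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- vector("list", 0L)
    bits <- bitwShiftL(1L, 0:(n - 2L))
    for (G in reps) {
      base <- matrix(0L, n, n)
      base[seq_len(n - 1L), seq_len(n - 1L)] <- G
      for (mask in seq_len(2L^(n - 1L) - 1L)) {
        sel <- which(bitwAnd(mask, bits) != 0L)
        A <- base
        A[n, sel] <- 1L
        A[sel, n] <- 1L
        key <- canonical_key(A)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- A
        }
      }
    }
    reps <- out
  }
  reps
}

# canonical upper-triangle string of an adjacency matrix (isomorphism invariant)
canonical_key <- function(A) {
  n <- nrow(A)
  e <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  g <- igraph::make_graph(as.vector(t(e)), n = n, directed = FALSE)
  lab <- igraph::canonical_permutation(g)$labeling
  Ac <- A[order(lab), order(lab)]
  rawToChar(as.raw(48L + Ac[upper.tri(Ac)]))
}

#' Thresholds for every small connected graph
#'
#' Computes cooperation thresholds for all connected graphs of the given
#' sizes (one row per isomorphism class) under the requested update rules
#' and games. The coalescence systems are solved once per graph and shared
#' across rule/game combinations.
#'
#' @param n_range sizes to enumerate, a subset of 3:8.
#' @param rules update rules to evaluate.
#' @param games games to evaluate.
#' @param payoff_scheme payoff scheme used for every combination.
#' @param progress print a line per size.
#' @return A data frame with columns `n`, `id`, `key` (canonical form),
#'   `edges`, and `<game>_<rule>` threshold values.
#' @export
census_thresholds <- function(n_range = 3:8, rules = c("pc", "db", "bd"),
                              games = c("pgg", "dg"),
                              payoff_scheme = "average", progress = FALSE) {
  stopifnot(all(n_range %in% 3:8))
  combos <- expand.grid(game = games, rule = rules, stringsAsFactors = FALSE)
  rows <- vector("list", 0L)
  for (n in sort(n_range)) {
    graphs <- enumerate_connected(n)
    if (progress) message("n = ", n, ": ", length(graphs), " graphs")
    vals <- matrix(NA_real_, length(graphs), nrow(combos))
    keys <- character(length(graphs))
    edges <- integer(length(graphs))
    for (gi in seq_along(graphs)) {
      A <- graphs[[gi]]
      net <- pgg_network(A, check_connected = FALSE)
      keys[gi] <- canonical_key(A)
      edges[gi] <- sum(A) %/% 2L
      tau <- solve_coalescence_times(net)
      tau_bd <- if ("bd" %in% rules) bd_meeting_times(net) else NULL
      for (ci in seq_len(nrow(combos))) {
        rule <- combos$rule[ci]
        pcf <- payoff_coefficients(net, combos$game[ci], payoff_scheme)
        s <- threshold_sums(net, rule, pcf, if (rule == "bd") tau_bd else tau)
        vals[gi, ci] <- threshold_value(s$benefit, s$cost)
      }
    }
    df <- data.frame(n = n, id = seq_along(graphs), key = keys, edges = edges,
                     stringsAsFactors = FALSE)
    for (ci in seq_len(nrow(combos))) {
      df[[paste(combos$game[ci], combos$rule[ci], sep = "_")]] <- vals[, ci]
    }
    rows[[length(rows) + 1L]] <- df
  }
  do.call(rbind, rows)
}

#' Classify the graph census by cooperation category
#'
#' Fractions of enumerated graphs whose threshold falls in each category
#' (`finite_supporting`: 0 < value <= 30; `strict`: 30 < value <= 1000;
#' `no_support`: negative or effectively infinite), pooled over sizes.
#'
#' @param n_range sizes to pool (default 3:8, the 12,111-graph census).
#' @param game,rule,payoff_scheme which threshold to classify.
#' @param census optional precomputed [census_thresholds()] table covering
#'   the requested sizes and combination (computed if missing).
#' @return Named numeric vector of fractions summing to 1.
#' @export
classify_census <- function(n_range = 3:8, game = "pgg", rule = "pc",
                            payoff_scheme = "average", census = NULL) {
  col <- paste(game, rule, sep = "_")
  if (is.null(census)) {
    census <- census_thresholds(n_range, rules = rule, games = game,
                                payoff_scheme = payoff_scheme)
  }
  stopifnot(col %in% names(census))
  v <- census[[col]][census$n %in% n_range]
  cats <- factor(categorize_threshold(v),
                 levels = c("finite_supporting", "strict", "no_support"))
  tab <- table(cats) / length(v)
  setNames(as.numeric(tab), names(tab))
}

#' Percentile rank of a network within its size class
#'
#' All enumerated graphs of the target's size are sorted by ascending
#' threshold value (smaller thresholds support cooperation more readily);
#' graphs with no finite supporting threshold sort last. Ties share the
#' minimal rank. Returns `100 * rank / total` for the isomorphism class of
#' the target.
#'
#' @param target a [pgg_network].
#' @param game,rule,payoff_scheme which threshold to rank by.
#' @param census optional precomputed [census_thresholds()] table.
#' @return Percentile in (0, 100].
#' @examples
#' \donttest{rank_percentile(make_star(7), rule = "pc")}
#' @export
rank_percentile <- function(target, game = "pgg", rule = "pc",
                            payoff_scheme = "average", census = NULL) {
  target <- as_pgg_network(target)
  n <- target$n_nodes
  col <- paste(game, rule, sep = "_")
  if (is.null(census)) {
    census <- census_thresholds(n, rules = rule, games = game,
                                payoff_scheme = payoff_scheme)
  }
  census <- census[census$n == n, ]
  key <- canonical_key(target$adjacency)
  row <- match(key, census$key)
  if (is.na(row)) stop("target size does not match the census")
  v <- census[[col]]
  supporting <- is.finite(v) & v > 0 & v <= 1000
  sortkey <- ifelse(supporting, v, Inf)
  mine <- sortkey[row]
  rank <- sum(sortkey < mine - 1e-9) + 1L
  100 * rank / length(v)
}
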