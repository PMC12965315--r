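#' Construct a network for public-goods-game analysis
#'
#' A `pgg_network` is a simple, undirected, unweighted graph stored as a
#' dense 0/1 adjacency matrix together with cached degrees. Every agent `i`
#' organises a group consisting of itself and its neighbours, of size
#' `k_i + 1`, and plays one public goods game per group it belongs to.
#'
#' @param adjacency square numeric/integer matrix; symmetric, zero diagonal,
#'   entries in `{0, 1}`.
#' @param check_connected if `TRUE` (default), warn when the graph is not
#'   connected. Threshold computations require connectivity and will error.
#' @return An object of class `pgg_network` with elements `adjacency`
#'   (integer matrix), `n_nodes` and `degrees`.
#' @examples
#' net <- pgg_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' net$degrees
#' @export
pgg_network <- function(adjacency, check_connected = TRUE) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (nrow(A) < 2) stop("a network needs at least 2 nodes")
  storage.mode(A) <- "integer"
  dimnames(A) <- NULL
  if (!all(A %in% c(0L, 1L))) stop("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0L)) stop("self-loops are not allowed")
  if (!identical(A, t(A))) stop("adjacency must be symmetric")
  net <- structure(
    list(adjacency = A, n_nodes = nrow(A), degrees = as.integer(rowSums(A))),
    class = "pgg_network"
  )
  if (any(net$degrees == 0L)) {
    if (check_connected) warning("network has isolated nodes")
  } else if (check_connected && !is_connected(net)) {
    warning("network is not connected")
  }
  net
}

as_pgg_network <- function(x, ...) {
  if (inherits(x, "pgg_network")) return(x)
  if (inherits(x, "igraph")) {
    return(pgg_network(igraph::as_adjacency_matrix(x, sparse = FALSE), ...))
  }
  if (is.matrix(x)) return(pgg_network(x, ...))
  stop("cannot interpret object as a network")
}

#' @export
print.pgg_network <- function(x, ...) {
  cat(sprintf(
    "pgg_network: %d nodes, %d edges, degrees %d..%d%s\n",
    x$n_nodes, sum(x$degrees) %/% 2L, min(x$degrees), max(x$degrees),
    if (is_connected(x)) "" else " (disconnected)"
  ))
  invisible(x)
}

#' Test whether a network is connected
#'
#' Breadth-first search from node 1.
#'
#' @param network a [pgg_network] (or adjacency matrix).
#' @return logical scalar.
#' @export
is_connected <- function(network) {
  A <- if (inherits(network, "pgg_network")) network$adjacency else network
  n <- nrow(A)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# neighbour index list (1-based)
adj_list <- function(network) {
  A <- network$adjacency
  lapply(seq_len(nrow(A)), function(i) which(A[i, ] == 1L))
}

as_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
}

#' Mean local clustering coefficient
#'
#' The abundance of triangles around a node: the fraction of pairs of its
#' neighbours that are themselves connected, averaged over nodes. Nodes of
#' degree below 2 contribute 0 to the mean.
#'
#' @param network a [pgg_network].
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' clustering_coefficient(make_star(5))      # 0, no triangles
#' clustering_coefficient(make_ceiling_fan(2))
#' @export
clustering_coefficient <- function(network) {
  network <- as_pgg_network(network)
  ct <- igraph::transitivity(as_igraph(network), type = "local", isolates = "zero")
  ct[network$degrees < 2L] <- 0
  mean(ct)
}

#' Read and write plain-text edge lists
#'
#' `read_edge_list()` parses a two-column text file of node label pairs
#' (whitespace- or comma-separated, `#` comments allowed). Labels are
#' arbitrary strings, mapped deterministically to node indices in sorted
#' order. Duplicate edges collapse; self-loops are an error; a disconnected
#' graph is read with a warning. `write_edge_list()` writes one edge per
#' line with 1-based integer labels, so a write/read round trip preserves
#' the graph up to node relabelling.
#'
#' @param path file path.
#' @return `read_edge_list()` returns a [pgg_network];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty edge-list file: ", path)
  toks <- strsplit(lines, "[,[:space:]]+")
  bad <- lengths(toks) != 2L
  if (any(bad)) stop("malformed edge-list line: '", lines[which(bad)[1]], "'")
  ends <- matrix(unlist(toks), ncol = 2, byrow = TRUE)
  if (any(ends[, 1] == ends[, 2])) {
    stop("self-loop in edge list: '", ends[which(ends[, 1] == ends[, 2])[1], 1], "'")
  }
  labels <- sort(unique(c(ends)))
  i <- match(ends[, 1], labels)
  j <- match(ends[, 2], labels)
  A <- matrix(0L, length(labels), length(labels))
  A[cbind(i, j)] <- 1L
  A[cbind(j, i)] <- 1L
  pgg_network(A)
}

#' @param network a [pgg_network] to write.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(network, path) {
  network <- as_pgg_network(network)
  e <- which(upper.tri(network$adjacency) & network$adjacency == 1L, arr.ind = TRUE)
  writeLines(paste(e[, 1], e[, 2]), path)
  invisible(path)
}

#' Read and write dense 0/1 adjacency matrices as CSV
#'
#' @param path file path.
#' @return `read_adjacency_csv()` returns a [pgg_network].
#' @export
read_adjacency_csv <- function(path) {
  A <- as.matrix(read.table(path, sep = ",", header = FALSE))
  pgg_network(A)
}

#' @param network a [pgg_network] to write.
#' @rdname read_adjacency_csv
#' @export
write_adjacency_csv <- function(network, path) {
  network <- as_pgg_network(network)
  write.table(network$adjacency, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
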