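# Interaction-network handling and topological module detection by spin-glass
# simulated annealing (Potts model with a configuration-model null; at
# resolution gamma = 1 minimizing the Hamiltonian is equivalent to maximizing
# Newman-Girvan modularity).

.ensure_names <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- sprintf("v%d", seq_len(igraph::vcount(g)))
  g
}

#' Load an undirected gene interaction network from an edge data.frame
#'
#' Self-loops are dropped and duplicate edges collapsed; both are counted.
#'
#' @param edges data.frame whose first two columns are gene ids (extra
#'   columns are ignored).
#' @return An igraph graph with attributes `n_self_loops` and
#'   `n_duplicate_edges`.
#' @export
load_network <- function(edges) {
  if (nrow(edges) == 0L) stop("empty edge list")
  e <- data.frame(from = as.character(edges[[1]]),
                  to = as.character(edges[[2]]), stringsAsFactors = FALSE)
  self <- e$from == e$to
  e <- e[!self, , drop = FALSE]
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  dup <- duplicated(key)
  g <- igraph::graph_from_data_frame(e[!dup, , drop = FALSE],
                                     directed = FALSE)
  g$n_self_loops <- sum(self)
  g$n_duplicate_edges <- sum(dup)
  message(sprintf("network: %d nodes, %d edges (%d self-loops dropped, %d duplicates collapsed)",
                  igraph::vcount(g), igraph::ecount(g), sum(self), sum(dup)))
  g
}

#' Largest connected component
#'
#' Ties in component size are broken deterministically in favour of the
#' component containing the lexicographically smallest node name.
#'
#' @param network an igraph graph with >= 1 node.
#' @return The induced subgraph on the largest component.
#' @export
largest_connected_component <- function(network) {
  stopifnot(igraph::vcount(network) >= 1L)
  network <- .ensure_names(network)
  comp <- igraph::components(network)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(b)
      min(igraph::V(network)$name[comp$membership == b]), character(1))
    big <- big[order(firsts)[1L]]
  }
  igraph::induced_subgraph(network,
                           which(comp$membership == big))
}

#' Spin-glass Hamiltonian of a partition
#'
#' `H = -sum_{i<j} (A_ij - gamma * k_i * k_j / (2m)) * delta(s_i, s_j)`.
#'
#' @param network igraph graph.
#' @param membership integer module label per node (graph vertex order).
#' @param gamma resolution parameter.
#' @return The Hamiltonian value.
#' @export
spinglass_hamiltonian <- function(network, membership, gamma = 1) {
  stopifnot(length(membership) == igraph::vcount(network))
  deg <- igraph::degree(network)
  two_m <- sum(deg)
  el <- igraph::as_edgelist(network, names = FALSE)
  same_edges <- sum(membership[el[, 1]] == membership[el[, 2]])
  K <- tapply(deg, membership, sum)
  null_pairs <- (sum(K^2) - sum(deg^2)) / 2
  -(same_edges - gamma * null_pairs / two_m)
}

#' Partition a connected network into topological modules
#'
#' Minimizes the spin-glass Hamiltonian by single-node-move simulated
#' annealing with geometric cooling, best of `restarts` independently seeded
#' runs, followed by a greedy polish. Empty spin states are dropped and
#' modules are relabeled in decreasing size order.
#'
#' @param network connected igraph graph (take the
#'   [largest_connected_component()] first; disconnected input is an error).
#' @param q maximum number of spin states (default 100; must be at least the
#'   plausible module count).
#' @param gamma resolution parameter (default 1: Newman-Girvan null).
#' @param t0 starting temperature; `0` (default) chooses it automatically so
#'   the initial acceptance rate is roughly one half.
#' @param cooling geometric cooling factor per sweep (default 0.99).
#' @param tmin stop temperature: annealing ends once a full sweep at
#'   `T < tmin` accepts no move (default 0.01).
#' @param restarts independent annealing runs; the minimum-H run is kept.
#' @param seed integer seed (each restart uses a derived sub-seed).
#' @return A `module_partition`: `membership` (named integer vector, module
#'   ids contiguous by decreasing size), `sizes`, `H` (final Hamiltonian),
#'   `modularity` (Newman-Girvan Q of the partition), and `parameters`.
#' @export
spinglass_partition <- function(network, q = 100L, gamma = 1, t0 = 0,
                                cooling = 0.99, tmin = 0.01,
                                restarts = 5L, seed = 1L) {
  if (igraph::vcount(network) < 1L) stop("empty graph")
  network <- .ensure_names(network)
  if (igraph::components(network)$no > 1L)
    stop("network is disconnected: partition the largest connected component")
  q <- min(as.integer(q), igraph::vcount(network))
  adj <- igraph::as_adj_list(network)
  deg <- lengths(adj)
  adj_flat <- as.integer(unlist(lapply(adj, as.integer)) - 1L)
  adj_start <- c(0L, cumsum(as.integer(deg)))

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(substream_seed(seed, 1000L + r))
    run <- .spinglass_anneal_cpp(adj_flat, adj_start, as.numeric(deg),
                                 q, gamma, t0, cooling, tmin)
    if (is.null(best) || run$H < best$H) best <- run
  }

  spin <- best$spin + 1L
  sizes <- sort(table(spin), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  membership <- setNames(unname(relabel[as.character(spin)]),
                         igraph::V(network)$name)
  structure(list(
    membership = membership,
    sizes = as.integer(table(membership)),
    H = best$H,
    modularity = igraph::modularity(network, membership),
    parameters = list(q = q, gamma = gamma, t0 = t0, cooling = cooling,
                      tmin = tmin, restarts = restarts, seed = seed)),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  s <- partition_summary(x)
  cat(sprintf("module_partition: %d modules over %d nodes (mean size %.1f, SD %.1f); H = %.3f, Q = %.3f\n",
              s$n_modules, sum(x$sizes), s$mean_size, s$sd_size,
              x$H, x$modularity))
  invisible(x)
}

#' Descriptive statistics of a module partition
#'
#' @param x a `module_partition`, or a numeric vector of module sizes.
#' @return data.frame with n_modules, mean_size, sd_size, min_size, max_size.
#' @export
partition_summary <- function(x) {
  sizes <- if (inherits(x, "module_partition")) x$sizes else as.numeric(x)
  stopifnot(length(sizes) >= 1L, all(sizes > 0))
  data.frame(n_modules = length(sizes),
             mean_size = mean(sizes),
             sd_size = if (length(sizes) > 1L) sd(sizes) else 0,
             min_size = min(sizes),
             max_size = max(sizes))
}
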