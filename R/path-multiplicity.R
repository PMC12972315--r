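#' Count all shortest paths between every node pair simultaneously
#'
#' Runs the matrix-power counting scheme: powers of the adjacency matrix
#' `A^k` count walks of length `k`, and the first power at which a pair
#' acquires a nonzero walk count gives both its shortest-path length
#' (`l_ij = k`) and its shortest-path count (`h_ij = (A^k)_ij`), because every
#' walk of minimal length is a path. A mask of still-unresolved off-diagonal
#' pairs restricts each deposit to newly resolved pairs, so diagonals stay
#' zero (closed walks are not paths) and lengths are true distances.
#'
#' The walk-count matrix is propagated in masked form: after each deposit,
#' only the freshly resolved layer (pairs at distance exactly `k`) is kept
#' before the next multiplication by `A`. Every predecessor of `j` on a
#' shortest `i`-`j` path of length `k + 1` lies at distance exactly `k` from
#' `i`, and a length-`k` walk to a vertex at distance below `k` can never
#' extend to a first arrival, so each deposited count is identical to the
#' literal power `A^k` entry while magnitudes stay at the scale of true path
#' counts instead of raw walk counts. Counts are held in doubles, which represent integers exactly
#' below 2^53; the iteration stops with an error if the next product could
#' exceed that range, rather than return inexact counts.
#'
#' @param g a connected undirected simple igraph object with `N >= 2` nodes.
#' @return an object of class `path_multiplicity`: list with `H` (N x N
#'   shortest-path counts, zero diagonal), `L` (N x N shortest-path lengths),
#'   and `k_max` (iterations executed; equals the diameter). Dimnames carry
#'   the original node labels.
#' @seealso [brute_force_count()] for the per-pair BFS oracle, [pmi()].
#' @export
count_shortest_paths <- function(g) {
  check_graph(g, min_nodes = 2L)
  n <- vcount(g)
  A <- as.matrix(as_adjacency_matrix(g, type = "both", sparse = TRUE))
  storage.mode(A) <- "double"
  max_deg <- max(rowSums(A))
  labs <- node_labels(g)

  H <- matrix(0, n, n)
  L <- matrix(0, n, n)
  unresolved <- !diag(n)   # logical mask of pairs with no count yet
  P <- A
  k <- 1L
  repeat {
    newly <- unresolved & (P > 0)
    H[newly] <- P[newly]
    L[newly] <- k
    unresolved <- unresolved & !newly
    if (!any(unresolved)) break
    if (k >= n - 1L) {
      stop("graph is disconnected: ", sum(unresolved) / 2,
           " node pair(s) unreachable; apply giant_component() first",
           call. = FALSE)
    }
    P <- P * newly   # keep only the freshly resolved layer (distance-k pairs)
    if (max(P) * max_deg >= 2^53) {
      stop("shortest-path counts exceed the exact integer range of doubles",
           call. = FALSE)
    }
    P <- P %*% A
    k <- k + 1L
  }
  dimnames(H) <- dimnames(L) <- list(labs, labs)
  structure(list(H = H, L = L, k_max = k), class = "path_multiplicity")
}

#' @exportS3Method base::print
print.path_multiplicity <- function(x, ...) {
  n <- nrow(x$H)
  cat("Path multiplicity matrices for", n, "nodes\n")
  cat("  diameter (k_max):", x$k_max, "\n")
  cat("  max PMA:", max(x$H), "  mean PMA:",
      format(sum(x$H) / (n * (n - 1)), digits = 6), "\n")
  invisible(x)
}

#' BFS shortest-path length and count for one node pair
#'
#' Independent per-pair oracle: a breadth-first layering from `i` with the
#' standard dynamic-programming accumulation of path counts over predecessor
#' layers (`sigma(v) = sum of sigma(u)` over neighbours `u` one layer closer
#' to the source). Used to validate [count_shortest_paths()]; it shares no
#' code with the matrix-power scheme.
#'
#' @param g an undirected igraph object.
#' @param i,j distinct vertex indices (1-based).
#' @return list with `length` and `count`.
#' @export
brute_force_count <- function(g, i, j) {
  check_graph(g, min_nodes = 2L)
  n <- vcount(g)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j || i < 1L || j < 1L || i > n || j > n) {
    stop("`i` and `j` must be distinct vertices of `g`", call. = FALSE)
  }
  res <- bfs_path_counts(igraph::as_adj_list(g), n, i)
  if (is.na(res$dist[j])) {
    stop("nodes ", i, " and ", j, " are not connected", call. = FALSE)
  }
  list(length = res$dist[j], count = res$sigma[j])
}

# Single-source BFS layering with path-count accumulation; `adj` is a
# precomputed adjacency list so callers can amortize it over many sources.
bfs_path_counts <- function(adj, n, source) {
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  dist[source] <- 0L
  sigma[source] <- 1
  frontier <- source
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- integer(0)
    for (u in frontier) {
      for (v in as.integer(adj[[u]])) {
        if (is.na(dist[v])) {
          dist[v] <- d
          nxt <- c(nxt, v)
          sigma[v] <- sigma[v] + sigma[u]
        } else if (dist[v] == d) {
          sigma[v] <- sigma[v] + sigma[u]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

#' Path multiplicity index (PMI)
#'
#' The mean number of shortest paths over all ordered node pairs,
#' `Phi = sum_{i != j} h_ij / (N(N-1))`. Equal to 1 exactly when every pair
#' has a unique shortest path (trees, chains, complete graphs).
#'
#' @inheritParams count_shortest_paths
#' @return object of class `pmi_result`: list with `phi`, `n_pairs`
#'   (= N(N-1)) and `k_max`.
#' @export
pmi <- function(g) {
  pm <- count_shortest_paths(g)
  n <- nrow(pm$H)
  structure(
    list(phi = sum(pm$H) / (n * (n - 1)), n_pairs = n * (n - 1),
         k_max = pm$k_max),
    class = "pmi_result"
  )
}

#' @exportS3Method base::print
print.pmi_result <- function(x, ...) {
  cat("PMI  Phi =", format(x$phi, digits = 8),
      " (", x$n_pairs, "ordered pairs )\n")
  invisible(x)
}

#' Relative path multiplicity index (RPMI)
#'
#' Normalizes the PMI of a graph by the mean PMI of an ensemble of
#' Erdos-Renyi G(N, M) graphs with the same number of nodes and exactly the
#' same number of edges, removing the size and density contribution:
#' `Phi_tilde = Phi(g) / mean(Phi(G_ER))`. Each ER realization is reduced to
#' its giant component before its PMI is taken; realizations whose giant
#' component has fewer than 2 nodes are redrawn (with a message), up to 100
#' attempts each.
#'
#' @inheritParams count_shortest_paths
#' @param ensemble_size number of ER realizations to average over.
#' @param seed integer seed making the ensemble fully reproducible.
#' @return object of class `rpmi_result`: list with `phi`, `phi_er_mean`,
#'   `phi_tilde`, `phi_er` (per-realization PMI values), `ensemble_size`,
#'   `seed`.
#' @export
rpmi <- function(g, ensemble_size = 50L, seed = 1L) {
  check_graph(g, connected = TRUE, min_nodes = 2L, remedy = "giant_component")
  if (ensemble_size < 1L) stop("`ensemble_size` must be >= 1", call. = FALSE)
  n <- vcount(g); m <- ecount(g)
  phi_g <- pmi(g)$phi
  phi_er <- with_seed(seed, {
    vapply(seq_len(ensemble_size), function(r) {
      for (try in 1:100) {
        gc <- giant_component(sample_gnm(n, m))
        if (vcount(gc) >= 2L) return(pmi(gc)$phi)
        message("ER realization with degenerate giant component; redrawing")
      }
      stop("could not draw a usable ER baseline graph", call. = FALSE)
    }, 0)
  })
  structure(
    list(phi = phi_g, phi_er_mean = mean(phi_er),
         phi_tilde = phi_g / mean(phi_er), phi_er = phi_er,
         ensemble_size = as.integer(ensemble_size), seed = seed),
    class = "rpmi_result"
  )
}

#' @exportS3Method base::print
print.rpmi_result <- function(x, ...) {
  cat("RPMI  Phi =", format(x$phi, digits = 6),
      "  Phi_ER =", format(x$phi_er_mean, digits = 6),
      "  Phi~ =", format(x$phi_tilde, digits = 6),
      " (ensemble", x$ensemble_size, ")\n")
  invisible(x)
}

#' Histogram of path multiplicity amounts
#'
#' Tabulates the PMA values `h_ij` over unordered node pairs.
#'
#' @param pm a `path_multiplicity` object (or a graph, which is counted
#'   first).
#' @return data frame with columns `h` and `count`; counts sum to
#'   `N(N-1)/2`.
#' @export
pma_histogram <- function(pm) {
  if (igraph::is_igraph(pm)) pm <- count_shortest_paths(pm)
  vals <- pm$H[upper.tri(pm$H)]
  tab <- table(vals)
  data.frame(h = as.numeric(names(tab)), count = as.vector(tab))
}
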