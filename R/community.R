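#' Modularity of a labelled partition
#'
#' `Q = (1/2M) sum_ij (a_ij - gamma k_i k_j / 2M) delta(c_i, c_j)`, the
#' fraction of within-community edges minus its expectation under the
#' degree-preserving null model, with resolution `gamma` scaling the null
#' term.
#'
#' @param g an undirected simple igraph object with at least one edge.
#' @param labels community label per vertex (any vector of length N).
#' @param gamma resolution parameter (default 1).
#' @return the modularity value, in `[-1, 1]`.
#' @export
modularity_q <- function(g, labels, gamma = 1) {
  check_graph(g)
  if (length(labels) != vcount(g)) {
    stop("`labels` must assign one community per vertex", call. = FALSE)
  }
  m <- ecount(g)
  if (m == 0L) stop("modularity undefined on an edgeless graph", call. = FALSE)
  labels <- as.integer(factor(labels))
  el <- as_edgelist(g, names = FALSE)
  within <- tabulate(labels[el[, 1]][labels[el[, 1]] == labels[el[, 2]]],
                     nbins = max(labels))
  ktot <- vapply(seq_len(max(labels)),
                 function(cc) sum(degree(g)[labels == cc]), 0)
  sum(within / m - gamma * (ktot / (2 * m))^2)
}

# Dense generalized modularity matrix B^(U) for a vertex subset.
# B_ij = A_ij - gamma k_i k_j / 2M restricted to U, minus a diagonal
# correction so every row sums to zero within U; for U = V the correction
# vanishes and B^(U) is the plain modularity matrix.
modularity_submatrix <- function(ctx, u, gamma = 1) {
  B <- as.matrix(ctx$A[u, u, drop = FALSE]) -
    gamma * outer(ctx$k[u], ctx$k[u]) / ctx$two_m
  diag(B) <- diag(B) - rowSums(B)
  B
}

modularity_ctx <- function(g) {
  list(A = as_adjacency_matrix(g, type = "both", sparse = TRUE),
       k = degree(g), two_m = 2 * ecount(g))
}

#' Implicit modularity-matrix product
#'
#' Computes `B^(U) x` using only a sparse adjacency product and two degree
#' inner products (`B x = A x - (k' x / 2M) k`, plus the generalized
#' diagonal correction on a subset), so each multiply costs `O(M + N)`.
#' Exists chiefly so the dense matrix used by the spectral split can be
#' validated against an independent formulation.
#'
#' @param g an undirected simple igraph object.
#' @param x numeric vector, one entry per vertex of `subset`.
#' @param subset vertex indices defining the restricted operator (default:
#'   all vertices).
#' @param gamma resolution parameter.
#' @return the product vector, same length as `x`.
#' @export
modularity_matvec <- function(g, x, subset = NULL, gamma = 1) {
  check_graph(g)
  ctx <- modularity_ctx(g)
  u <- if (is.null(subset)) seq_len(vcount(g)) else as.integer(subset)
  if (length(x) != length(u)) stop("`x` must match `subset` length", call. = FALSE)
  Au <- ctx$A[u, u, drop = FALSE]
  ku <- ctx$k[u]
  # row sums of B^(U) before the diagonal correction
  d <- Matrix::rowSums(Au) - gamma * ku * sum(ku) / ctx$two_m
  as.numeric(Au %*% x) - gamma * ku * sum(ku * x) / ctx$two_m - d * x
}

#' Spectral bipartition of a vertex subset
#'
#' Leading-eigenvector split: takes the dominant eigenvector `u1` of the
#' generalized modularity matrix restricted to `subset` and assigns
#' `s_i = sign(u1_i)` (zero entries get +1, with a message). The subset is
#' declared indivisible when the leading eigenvalue is not positive (within
#' tolerance). The eigenvector sign is fixed so its first nonzero entry is
#' positive, making the split deterministic across linear-algebra backends.
#'
#' @param g an undirected simple igraph object.
#' @param subset vertex indices (default all); at least 2.
#' @param gamma resolution parameter.
#' @param tol indivisibility threshold on the leading eigenvalue.
#' @return list with `s` (+/-1 per subset vertex, or `NULL` if indivisible),
#'   `lambda` (leading eigenvalue), `indivisible` (logical).
#' @export
leading_eigenvector_split <- function(g, subset = NULL, gamma = 1, tol = 1e-12) {
  check_graph(g)
  u <- if (is.null(subset)) seq_len(vcount(g)) else as.integer(subset)
  if (length(u) < 2L) stop("`subset` must contain at least 2 vertices", call. = FALSE)
  B <- modularity_submatrix(modularity_ctx(g), u, gamma)
  split_from_bmat(B)
}

split_from_bmat <- function(B, tol = 1e-12) {
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values[1L]
  if (lambda <= tol) {
    return(list(s = NULL, lambda = lambda, indivisible = TRUE))
  }
  u1 <- e$vectors[, 1L]
  nz <- which(abs(u1) > 1e-12)
  if (length(nz) > 0L && u1[nz[1L]] < 0) u1 <- -u1
  if (any(abs(u1) <= 1e-12)) {
    message("eigenvector entries at zero assigned to the +1 group")
  }
  s <- ifelse(u1 >= 0, 1, -1)
  list(s = s, lambda = lambda, indivisible = FALSE)
}

#' Single-vertex refinement of a bipartition
#'
#' Kernighan--Lin-style polishing of a +/-1 split: in each pass every vertex
#' is moved at most once, in order of largest modularity change, and the best
#' prefix of the move sequence is kept; passes repeat until no positive gain
#' remains. The returned split never has lower modularity than the input.
#'
#' @inheritParams leading_eigenvector_split
#' @param s numeric vector of +/-1, one per subset vertex.
#' @return refined vector of +/-1.
#' @export
kl_refine <- function(g, subset = NULL, s, gamma = 1) {
  check_graph(g)
  u <- if (is.null(subset)) seq_len(vcount(g)) else as.integer(subset)
  if (length(s) != length(u) || !all(s %in% c(-1, 1))) {
    stop("`s` must be a +/-1 vector over `subset`", call. = FALSE)
  }
  B <- modularity_submatrix(modularity_ctx(g), u, gamma)
  refine_bipartition(B, s, ecount(g))
}

# Core refinement on a precomputed B^(U); M is the whole-graph edge count.
# Flipping s_i changes Q by (B_ii - s_i (Bs)_i)/M; Bs is updated in O(|U|)
# per move.
refine_bipartition <- function(B, s, m, tol = 1e-12) {
  nu <- length(s)
  repeat {
    scur <- s
    Bs <- as.numeric(B %*% scur)
    moved <- logical(nu)
    order_flipped <- integer(nu)
    cum <- 0
    best <- 0
    best_prefix <- 0L
    for (step in seq_len(nu)) {
      gains <- (diag(B) - scur * Bs) / m
      gains[moved] <- -Inf
      i <- which.max(gains)   # ties -> smallest index: deterministic
      cum <- cum + gains[i]
      s_old <- scur[i]
      scur[i] <- -s_old
      Bs <- Bs - 2 * s_old * B[, i]
      moved[i] <- TRUE
      order_flipped[step] <- i
      if (cum > best + tol) {
        best <- cum
        best_prefix <- step
      }
    }
    if (best_prefix == 0L) return(s)
    s[order_flipped[seq_len(best_prefix)]] <-
      -s[order_flipped[seq_len(best_prefix)]]
  }
}

#' Community detection by recursive leading-eigenvector modularity
#'
#' Deterministic spectral modularity maximization: the graph is recursively
#' bipartitioned with [leading_eigenvector_split()] followed by
#' [kl_refine()], and a subdivision is accepted only when it strictly
#' increases modularity (evaluated through the generalized modularity matrix,
#' whose zero row sums make the undivided state exactly neutral). Recursion
#' stops when every group is indivisible. Two runs on the same graph yield
#' identical partitions.
#'
#' @param g a connected undirected simple igraph object.
#' @param gamma resolution parameter (default 1).
#' @param tol minimum modularity gain for accepting a subdivision.
#' @return object of class `community_partition`: list with `membership`
#'   (community id per vertex, numbered by smallest member vertex), `n_c`,
#'   `Q` (recomputed from the final labels via [modularity_q()]), `gamma`.
#' @export
detect_communities <- function(g, gamma = 1, tol = 1e-10) {
  check_graph(g, connected = TRUE, min_nodes = 1L, remedy = "giant_component")
  n <- vcount(g)
  if (ecount(g) == 0L) {
    return(structure(list(membership = 1L, n_c = 1L, Q = NA_real_,
                          gamma = gamma), class = "community_partition"))
  }
  ctx <- modularity_ctx(g)
  m <- ecount(g)
  final <- list()
  queue <- list(seq_len(n))
  while (length(queue) > 0L) {
    u <- queue[[1L]]
    queue <- queue[-1L]
    if (length(u) < 2L) {
      final[[length(final) + 1L]] <- u
      next
    }
    B <- modularity_submatrix(ctx, u, gamma)
    sp <- split_from_bmat(B)
    if (sp$indivisible) {
      final[[length(final) + 1L]] <- u
      next
    }
    s <- refine_bipartition(B, sp$s, m)
    dq <- as.numeric(s %*% B %*% s) / (4 * m)
    if (dq > tol && any(s > 0) && any(s < 0)) {
      queue <- c(queue, list(u[s > 0]), list(u[s < 0]))
    } else {
      final[[length(final) + 1L]] <- u
    }
  }
  # number communities by their smallest member vertex
  final <- final[order(vapply(final, min, 0L))]
  membership <- integer(n)
  for (cc in seq_along(final)) membership[final[[cc]]] <- cc
  structure(
    list(membership = membership, n_c = length(final),
         Q = modularity_q(g, membership, gamma), gamma = gamma),
    class = "community_partition"
  )
}

#' @exportS3Method base::print
print.community_partition <- function(x, ...) {
  cat("Partition: n_c =", x$n_c, "  Q =", format(x$Q, digits = 6),
      "  gamma =", x$gamma, "\n")
  invisible(x)
}

#' Community detection via external igraph algorithms
#'
#' Pass-throughs to [igraph]'s Walktrap, Louvain, label-propagation and
#' Infomap implementations, provided for robustness comparisons only; they
#' are not part of this package's verified leading-eigenvector core.
#'
#' @param g a connected undirected simple igraph object.
#' @param method which igraph algorithm to delegate to.
#' @return a `community_partition` object (with `method` noted).
#' @export
detect_communities_external <- function(g, method = c("walktrap", "louvain",
                                                      "label_prop", "infomap")) {
  method <- match.arg(method)
  check_graph(g, connected = TRUE, remedy = "giant_component")
  comm <- switch(method,
    walktrap = igraph::cluster_walktrap(g),
    louvain = igraph::cluster_louvain(g),
    label_prop = igraph::cluster_label_prop(g),
    infomap = igraph::cluster_infomap(g)
  )
  mem <- as.integer(igraph::membership(comm))
  structure(
    list(membership = mem, n_c = length(unique(mem)),
         Q = modularity_q(g, mem), gamma = 1, method = method),
    class = "community_partition"
  )
}
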