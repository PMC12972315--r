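# Synthetic graph generators: the GKK static scale-free model, the Tribal
# Scale-Free (TSF) planted-community model, and reference models (ER, NW,
# BA, CBA, ring lattice).

#' GKK static scale-free graph
#'
#' The static model of Goh, Kahng and Kim: vertex `v` (v = 1..n) carries
#' weight `p_v` proportional to `v^-alpha`; vertex pairs are drawn by these
#' normalized weights and the edge is added unless it already exists, until
#' `m_target` edges are present. The resulting degree distribution has a
#' power-law tail with exponent `lambda = (1 + alpha)/alpha`; `alpha = 0` is
#' the homogeneous (ER-like) limit.
#'
#' @param n number of vertices.
#' @param m_target number of edges; at most `n(n-1)/2`.
#' @param alpha weight exponent in `[0, 1)`.
#' @param seed optional integer seed.
#' @return an undirected simple igraph object with `n` vertices (possibly
#'   with isolates) and `m_target` edges.
#' @export
gkk_static <- function(n, m_target, alpha, seed = NULL) {
  if (alpha < 0 || alpha >= 1) stop("`alpha` must be in [0, 1)", call. = FALSE)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (m_target > n * (n - 1) / 2) {
    stop("`m_target` exceeds the number of vertex pairs", call. = FALSE)
  }
  with_seed(seed, {
    w <- (seq_len(n))^(-alpha)
    w <- w / sum(w)
    adj <- new.env(hash = TRUE, parent = emptyenv())
    edges <- matrix(0L, nrow = m_target, ncol = 2L)
    got <- 0L
    draws <- 0L
    max_draws <- 200L * m_target + 1e5
    while (got < m_target) {
      batch <- max(2L * (m_target - got), 64L)
      i <- sample.int(n, batch, replace = TRUE, prob = w)
      j <- sample.int(n, batch, replace = TRUE, prob = w)
      draws <- draws + batch
      keep <- which(i != j)
      for (t in keep) {
        a <- min(i[t], j[t]); b <- max(i[t], j[t])
        key <- paste0(a, "_", b)
        if (!exists(key, envir = adj, inherits = FALSE)) {
          assign(key, TRUE, envir = adj)
          got <- got + 1L
          edges[got, ] <- c(a, b)
          if (got == m_target) break
        }
      }
      if (draws > max_draws) {
        stop("GKK sampling stalled: target density infeasible for alpha = ",
             alpha, call. = FALSE)
      }
    }
    g <- make_empty_graph(n, directed = FALSE)
    g <- add_edges(g, t(edges))
    set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  })
}

#' Tribal Scale-Free (TSF) planted-community graph
#'
#' Generates a connected modular network: `n` nodes are assigned at random to
#' `n_c` near-equal communities ("tribes"); each community internally is a
#' GKK static scale-free subnet with a common weight exponent `alpha` and a
#' mean intra-community degree of `intra_degree`; communities are then joined
#' into one component by adding `n_e` uniformly chosen cross edges per
#' joining step (first between two random communities, then each remaining
#' community to a random already-connected one), for exactly
#' `n_e * (n_c - 1)` inter-community edges in total.
#'
#' Each subnet is drawn conditionally on being internally connected (an
#' unconditioned GKK draw can leave isolated low-weight vertices, which
#' would disconnect the union); together with the joining step this
#' guarantees a single connected component while keeping the edge-count
#' identity exact.
#'
#' @param n total number of nodes.
#' @param n_c number of planted communities (each of size >= 2).
#' @param intra_degree target mean degree inside each community (default 6).
#' @param alpha GKK weight exponent shared across communities (default 0.5,
#'   i.e. degree exponent 3).
#' @param n_e inter-community edges added per joining step (default 2).
#' @param seed optional integer seed.
#' @param max_retries per-subnet redraw budget for the connectivity
#'   conditioning.
#' @return object of class `tsf_graph`: list with `graph`, `membership`
#'   (planted labels), `intra_edges` and `inter_edges` (2-column matrices),
#'   `sizes`, and the generating parameters.
#' @export
tsf_graph <- function(n, n_c, intra_degree = 6, alpha = 0.5, n_e = 2L,
                      seed = NULL, max_retries = 50L) {
  if (n_c < 1L) stop("`n_c` must be >= 1", call. = FALSE)
  if (n_e < 1L) stop("`n_e` must be >= 1", call. = FALSE)
  sizes <- rep(n %/% n_c, n_c) + (seq_len(n_c) <= n %% n_c)
  if (any(sizes < 2L)) {
    stop("community sizes below 2; decrease `n_c`", call. = FALSE)
  }
  if (n_c > 1L && n_e > min(sizes)^2) {
    stop("`n_e` exceeds the number of available cross pairs", call. = FALSE)
  }
  with_seed(seed, {
    draw <- tsf_draw_once(n, n_c, sizes, intra_degree, alpha, n_e, max_retries)
    draw$alpha <- alpha
    draw$n_e <- as.integer(n_e)
    draw$n_c <- as.integer(n_c)
    stopifnot(is_connected(draw$graph))
    structure(draw, class = "tsf_graph")
  })
}

# One GKK subnet conditioned on internal connectivity.
gkk_connected <- function(sz, m_i, alpha, max_retries) {
  if (m_i < sz - 1L) {
    stop("`intra_degree` too low for a connected subnet of size ", sz,
         call. = FALSE)
  }
  for (try in seq_len(max_retries)) {
    sub <- gkk_static(sz, m_i, alpha)
    if (is_connected(sub)) return(sub)
  }
  stop("could not draw a connected subnet in ", max_retries,
       " attempts; increase `intra_degree`", call. = FALSE)
}

tsf_draw_once <- function(n, n_c, sizes, intra_degree, alpha, n_e,
                          max_retries = 50L) {
  membership <- integer(n)
  perm <- sample.int(n)
  groups <- split(perm, rep(seq_len(n_c), sizes))
  for (cc in seq_len(n_c)) membership[groups[[cc]]] <- cc

  intra <- matrix(0L, 0L, 2L)
  for (cc in seq_len(n_c)) {
    sz <- sizes[cc]
    m_i <- min(round(intra_degree * sz / 2), sz * (sz - 1) / 2)
    sub <- gkk_connected(sz, m_i, alpha, max_retries)
    el <- as_edgelist(sub, names = FALSE)
    if (nrow(el) > 0L) {
      intra <- rbind(intra, cbind(groups[[cc]][el[, 1]], groups[[cc]][el[, 2]]))
    }
  }

  inter <- matrix(0L, 0L, 2L)
  if (n_c > 1L) {
    connected <- sample.int(n_c, 1L)
    remaining <- setdiff(seq_len(n_c), connected)
    # first join: a second community chosen at random, then iterative attachment
    while (length(remaining) > 0L) {
      cm <- pick_one(remaining)
      anchor <- pick_one(connected)
      inter <- rbind(inter, cross_edges(groups[[cm]], groups[[anchor]], n_e))
      connected <- c(connected, cm)
      remaining <- setdiff(remaining, cm)
    }
  }

  g <- make_empty_graph(n, directed = FALSE)
  g <- add_edges(g, t(rbind(intra, inter)))
  g <- set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  list(graph = g, membership = membership, intra_edges = intra,
       inter_edges = inter, sizes = sizes)
}

# n_e distinct cross pairs between two node sets, endpoints uniform.
cross_edges <- function(va, vb, n_e, max_tries = 1000L) {
  seen <- character(0)
  out <- matrix(0L, n_e, 2L)
  got <- 0L
  for (try in seq_len(max_tries)) {
    a <- pick_one(va); b <- pick_one(vb)
    key <- paste0(a, "_", b)
    if (!key %in% seen) {
      seen <- c(seen, key)
      got <- got + 1L
      out[got, ] <- c(a, b)
      if (got == n_e) return(out)
    }
  }
  stop("could not draw ", n_e, " distinct cross edges", call. = FALSE)
}

#' @exportS3Method base::print
print.tsf_graph <- function(x, ...) {
  cat("TSF graph: N =", vcount(x$graph), " M =", ecount(x$graph),
      " n_c =", x$n_c, " n_e =", x$n_e, " alpha =", x$alpha, "\n")
  cat("  intra edges:", nrow(x$intra_edges),
      " inter edges:", nrow(x$inter_edges), "\n")
  invisible(x)
}

#' Reference random-graph generators
#'
#' Seeded wrappers for the classical models used as baselines:
#' `er_graph()` draws G(N, M) (or G(N, p) when `p` is given);
#' `rrl_graph()` is the regular ring lattice with each node linked to its
#' `k` nearest ring neighbours (`k` even; `k = 2` is the cycle);
#' `nw_graph()` is the Newman-Watts small world: a ring lattice plus added
#' shortcuts (no removal), either each lattice edge spawning a shortcut with
#' probability `p_add` or exactly `n_add` shortcuts;
#' `ba_graph()` is Barabasi-Albert preferential attachment with `m` edges
#' per new node (`m = 1` gives a tree);
#' `cba_graph()` is the clustered BA variant: after each preferential
#' attachment, additional links close a triangle with a random neighbour of
#' the last target with probability `p_triad`.
#'
#' @param n number of vertices.
#' @param m number of edges (`er_graph`) or edges per new node
#'   (`ba_graph`/`cba_graph`).
#' @param p,p_add,p_triad model probabilities.
#' @param k ring-neighbour count (even).
#' @param n_add exact shortcut count for `nw_graph` (overrides `p_add`).
#' @param seed optional integer seed.
#' @return an undirected simple igraph object.
#' @name reference_generators
NULL

#' @rdname reference_generators
#' @export
er_graph <- function(n, m = NULL, p = NULL, seed = NULL) {
  if (is.null(m) == is.null(p)) {
    stop("give exactly one of `m` or `p`", call. = FALSE)
  }
  with_seed(seed, {
    if (!is.null(m)) sample_gnm(n, m) else sample_gnp(n, p)
  })
}

#' @rdname reference_generators
#' @export
rrl_graph <- function(n, k) {
  if (k %% 2 != 0 || k < 2) stop("`k` must be even and >= 2", call. = FALSE)
  if (k >= n) stop("`k` must be < n", call. = FALSE)
  g <- make_ring(n)
  if (k > 2) g <- connect(g, k / 2)
  simplify(g)
}

#' @rdname reference_generators
#' @export
nw_graph <- function(n, k, p_add = NULL, n_add = NULL, seed = NULL) {
  g <- rrl_graph(n, k)
  with_seed(seed, {
    n_short <- if (!is.null(n_add)) as.integer(n_add)
               else rbinom(1L, ecount(g), p_add)
    added <- 0L
    guard <- 0L
    while (added < n_short) {
      guard <- guard + 1L
      if (guard > 200L * n_short + 1000L) {
        stop("cannot place ", n_short, " shortcuts", call. = FALSE)
      }
      pair <- sample.int(n, 2L)
      if (!are_adjacent(g, pair[1L], pair[2L])) {
        g <- add_edges(g, pair)
        added <- added + 1L
      }
    }
    g
  })
}

#' @rdname reference_generators
#' @export
ba_graph <- function(n, m, seed = NULL) {
  if (m < 1L || m >= n) stop("need 1 <= m < n", call. = FALSE)
  with_seed(seed, simplify(sample_pa(n, m = m, directed = FALSE)))
}

#' @rdname reference_generators
#' @export
cba_graph <- function(n, m, p_triad = 0.5, seed = NULL) {
  if (m < 1L || m >= n) stop("need 1 <= m < n", call. = FALSE)
  with_seed(seed, {
    n0 <- m + 1L
    edges <- t(utils::combn(n0, 2L))       # complete seed graph
    deg <- integer(n)
    deg[seq_len(n0)] <- n0 - 1L
    nbrs <- lapply(seq_len(n), function(v) integer(0))
    for (v in seq_len(n0)) nbrs[[v]] <- setdiff(seq_len(n0), v)
    for (v in seq((n0 + 1L), n)) {
      targets <- integer(0)
      last <- 0L
      while (length(targets) < m) {
        do_triad <- last > 0L && runif(1) < p_triad &&
          length(setdiff(nbrs[[last]], c(targets, v))) > 0L
        if (do_triad) {
          t_new <- pick_one(setdiff(nbrs[[last]], c(targets, v)))
        } else {
          # preferential attachment: weight by degree
          pool <- setdiff(which(deg > 0L), c(targets, v))
          t_new <- pool[sample.int(length(pool), 1L, prob = deg[pool])]
        }
        targets <- c(targets, t_new)
        last <- t_new
      }
      for (t_new in targets) {
        edges <- rbind(edges, c(v, t_new))
        deg[v] <- deg[v] + 1L
        deg[t_new] <- deg[t_new] + 1L
        nbrs[[v]] <- c(nbrs[[v]], t_new)
        nbrs[[t_new]] <- c(nbrs[[t_new]], v)
      }
    }
    g <- make_empty_graph(n, directed = FALSE)
    simplify(add_edges(g, t(edges)))
  })
}

#' Generate a model graph matched in size and density to a reference
#'
#' Produces a graph from the requested model with the same node count as
#' `g_ref` and an edge count as close as the model's granularity permits:
#' exact for ER and TSF, `m * N`-granular for BA/CBA, lattice-plus-shortcut
#' for NW. TSF structural parameters (`n_c`, `n_e`, `alpha`) are free and
#' taken from `...`; its intra-community degree is derived from the target
#' edge count.
#'
#' @param g_ref a connected reference graph.
#' @param model one of `"er"`, `"nw"`, `"ba"`, `"cba"`, `"tsf"`.
#' @param seed optional integer seed.
#' @param ... model-specific parameters (e.g. `n_c`, `n_e`, `alpha` for
#'   `"tsf"`; `p_triad` for `"cba"`).
#' @return an igraph object (for `"tsf"`, the `graph` element of the draw).
#' @export
match_reference <- function(g_ref, model = c("er", "nw", "ba", "cba", "tsf"),
                            seed = NULL, ...) {
  model <- match.arg(model)
  check_graph(g_ref, connected = TRUE, min_nodes = 3L)
  n <- vcount(g_ref); m <- ecount(g_ref)
  dots <- list(...)
  switch(model,
    er = er_graph(n, m = m, seed = seed),
    ba = ba_graph(n, m = max(1L, round(m / n)), seed = seed),
    cba = cba_graph(n, m = max(1L, round(m / n)),
                    p_triad = dots$p_triad %||% 0.5, seed = seed),
    nw = {
      k <- max(2L, 2L * ((m %/% n) %/% 1L))
      k <- min(k, if (n %% 2 == 0) n - 2L else n - 1L)
      extra <- m - n * k / 2
      if (extra < 0L) stop("reference too sparse for a ring lattice match",
                           call. = FALSE)
      nw_graph(n, k, n_add = extra, seed = seed)
    },
    tsf = {
      n_c <- dots$n_c %||% 8L
      n_e <- dots$n_e %||% 2L
      alpha <- dots$alpha %||% 0.5
      m_intra <- m - n_e * (n_c - 1L)
      if (m_intra < n) stop("reference too sparse for a TSF match", call. = FALSE)
      tsf_graph(n, n_c, intra_degree = 2 * m_intra / n, alpha = alpha,
                n_e = n_e, seed = seed)$graph
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
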