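# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Stop unless `g` is an igraph object; optionally require connectivity and a
# minimum order. `remedy` names the function to suggest for disconnected input.
check_graph <- function(g, connected = FALSE, min_nodes = 1L, remedy = NULL) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("`g` must be undirected", call. = FALSE)
  if (vcount(g) < min_nodes) {
    stop("graph must have at least ", min_nodes, " nodes", call. = FALSE)
  }
  if (connected && vcount(g) > 0L && !is_connected(g)) {
    msg <- "graph is disconnected"
    if (!is.null(remedy)) msg <- paste0(msg, "; apply ", remedy, "() first")
    stop(msg, call. = FALSE)
  }
  invisible(g)
}

# Node display labels: `name` vertex attribute if present, else 1..N.
node_labels <- function(g) {
  nm <- vertex_attr(g, "name")
  if (is.null(nm)) as.character(seq_len(vcount(g))) else as.character(nm)
}

# Uniformly pick one element of an index vector (avoids sample()'s scalar trap).
pick_one <- function(idx) idx[sample.int(length(idx), 1L)]
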