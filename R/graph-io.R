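#' Read an undirected simple graph from a file
#'
#' Reads plain edge lists (Network Repository dialect), Matrix Market sparse
#' adjacency files (`.mtx`) and GraphML. Whatever the source, the result is a
#' simple undirected graph: self-loops and duplicate (including reciprocal)
#' edges are dropped, with a message stating how many. Original node labels are
#' kept in the `name` vertex attribute; internally nodes are relabelled to a
#' dense index.
#'
#' The edge-list dialect accepts whitespace or comma separators, `#` and `%`
#' comment lines, blank lines, and an optional third column (a weight), which
#' is ignored.
#'
#' @param path path to the graph file.
#' @param format one of `"auto"` (from the file extension), `"edgelist"`,
#'   `"mtx"`, `"graphml"`.
#' @param allow_weights if `FALSE` (default), a Matrix Market file with
#'   non-unit numeric entries is rejected; if `TRUE` the weights are discarded
#'   with a message.
#' @return an [igraph::igraph] undirected simple graph.
#' @seealso [write_network()], [giant_component()]
#' @export
read_network <- function(path, format = c("auto", "edgelist", "mtx", "graphml"),
                         allow_weights = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", graphml = "graphml", "edgelist")
  }
  g <- switch(format,
    edgelist = read_edgelist_file(path),
    mtx      = read_mtx_file(path, allow_weights = allow_weights),
    graphml  = {
      gg <- igraph::read_graph(path, format = "graphml")
      if (is_directed(gg)) gg <- as_undirected(gg, mode = "collapse")
      gg
    }
  )
  make_simple(g)
}

read_edgelist_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#%].*)?$", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  nt <- lengths(toks)
  bad <- which(nt < 2L | nt > 3L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", idx[bad[1L]], " in ", path,
         ": expected 2 or 3 fields, got ", nt[bad[1L]], call. = FALSE)
  }
  ends <- cbind(vapply(toks, `[`, "", 1L), vapply(toks, `[`, "", 2L))
  graph_from_edgelist(ends, directed = FALSE)
}

read_mtx_file <- function(path, allow_weights = FALSE) {
  header <- tolower(readLines(path, n = 1L))
  if (!grepl("^%%matrixmarket\\s+matrix\\s+coordinate", header)) {
    stop("not a Matrix Market coordinate file: ", path, call. = FALSE)
  }
  weighted <- !grepl("pattern", header)
  m <- Matrix::readMM(path)
  if (nrow(m) != ncol(m)) {
    stop("Matrix Market adjacency must be square, got ",
         nrow(m), " x ", ncol(m), call. = FALSE)
  }
  tm <- methods::as(m, "TsparseMatrix")
  i <- tm@i + 1L
  j <- tm@j + 1L
  if (weighted) {
    x <- tm@x
    if (any(x != 1)) {
      if (!allow_weights) {
        stop("Matrix Market file carries edge weights; pass ",
             "`allow_weights = TRUE` to discard them", call. = FALSE)
      }
      message("discarding ", sum(x != 1), " non-unit edge weights")
    }
  }
  g <- make_empty_graph(nrow(m), directed = FALSE)
  g <- add_edges(g, rbind(i, j))
  set_vertex_attr(g, "name", value = as.character(seq_len(nrow(m))))
}

# Collapse to a simple graph, reporting what was dropped.
make_simple <- function(g) {
  before <- ecount(g)
  g <- simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- before - ecount(g)
  if (dropped > 0L) {
    message("dropped ", dropped, " self-loop/duplicate edge(s)")
  }
  if (is.null(vertex_attr(g, "name"))) {
    g <- set_vertex_attr(g, "name", value = as.character(seq_len(vcount(g))))
  }
  g
}

#' Write a graph to a file
#'
#' Inverse of [read_network()]: edge list (two space-separated label columns),
#' Matrix Market `coordinate pattern symmetric`, or GraphML. Reading the file
#' back reproduces the graph up to node relabelling.
#'
#' @param g an undirected igraph object.
#' @param path output path.
#' @inheritParams read_network
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("auto", "edgelist", "mtx", "graphml")) {
  format <- match.arg(format)
  check_graph(g)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", graphml = "graphml", "edgelist")
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- as_edgelist(g, names = FALSE)
  if (format == "edgelist") {
    labs <- node_labels(g)
    out <- c("# source target", sprintf("%s %s", labs[el[, 1]], labs[el[, 2]]))
    writeLines(out, path)
  } else {
    # lower-triangular coordinates as the symmetric-storage convention requires
    lo <- pmax(el[, 1], el[, 2])
    hi <- pmin(el[, 1], el[, 2])
    out <- c(
      "%%MatrixMarket matrix coordinate pattern symmetric",
      sprintf("%d %d %d", vcount(g), vcount(g), ecount(g)),
      sprintf("%d %d", lo, hi)
    )
    writeLines(out, path)
  }
  invisible(path)
}

#' Extract the giant connected component
#'
#' Returns the induced subgraph on the largest connected node set. When
#' several components tie for the largest size, the one containing the
#' smallest vertex index is returned. All analyses in this package operate on
#' connected graphs, so disconnected input should pass through here first.
#'
#' @param g an undirected igraph object with at least one node.
#' @return a connected igraph object.
#' @export
giant_component <- function(g) {
  check_graph(g, min_nodes = 1L)
  comp <- components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    first_node <- vapply(big, function(cc) min(which(comp$membership == cc)), 0)
    big <- big[which.min(first_node)]
  }
  induced_subgraph(g, which(comp$membership == big))
}

#' Edge density of a graph
#'
#' The fraction of realized node pairs, `p = <k>/(N-1) = 2M/(N(N-1))`, where
#' `<k>` is the average degree.
#'
#' @param g an undirected simple igraph object with at least 2 nodes.
#' @return a fraction in `[0, 1]`.
#' @export
edge_density_frac <- function(g) {
  check_graph(g, min_nodes = 2L)
  n <- vcount(g)
  2 * ecount(g) / (n * (n - 1))
}

#' Classical topology metrics of a connected graph
#'
#' Computes the standard whole-graph summary used alongside path multiplicity:
#' edge density `p`, average degree, average shortest path length (mean of
#' `d_ij` over ordered pairs, identical to the unordered mean on undirected
#' graphs), global efficiency (mean of `1/d_ij`), diameter, degree
#' assortativity, average local clustering coefficient (degree-<2 nodes count
#' as 0), and the k-shell index (maximum k-core index, i.e. the degeneracy).
#' Optionally also the community number from [detect_communities()].
#'
#' @param g a connected undirected simple igraph object, at least 2 nodes.
#' @param communities if `TRUE`, run [detect_communities()] and include `n_c`.
#' @return an object of class `metric_report`: a named list with elements
#'   `n`, `m`, `p`, `avg_degree`, `l_avg`, `e_glob`, `diameter`,
#'   `assortativity`, `clustering`, `k_shell` and `n_c` (`NA` unless
#'   `communities = TRUE`).
#' @export
classical_metrics <- function(g, communities = FALSE) {
  check_graph(g, connected = TRUE, min_nodes = 2L, remedy = "giant_component")
  n <- vcount(g)
  d <- distances(g)
  off <- d[upper.tri(d)]
  rep <- list(
    n = n,
    m = ecount(g),
    p = edge_density_frac(g),
    avg_degree = 2 * ecount(g) / n,
    l_avg = mean(off),
    e_glob = mean(1 / off),
    diameter = max(off),
    assortativity = assortativity_degree(g),
    clustering = transitivity(g, type = "localaverage", isolates = "zero"),
    k_shell = max(coreness(g)),
    n_c = NA_integer_
  )
  if (communities) {
    rep$n_c <- detect_communities(g)$n_c
  }
  structure(rep, class = "metric_report")
}

#' @exportS3Method base::print
print.metric_report <- function(x, ...) {
  cat("Graph metrics: N =", x$n, " M =", x$m, "\n")
  cat(sprintf("  density p = %.4g   <k> = %.4g\n", x$p, x$avg_degree))
  cat(sprintf("  L_avg = %.4g   E_glob = %.4g   diameter = %g\n",
              x$l_avg, x$e_glob, x$diameter))
  cat(sprintf("  assortativity r = %.4g   clustering C = %.4g   k_s = %d\n",
              x$assortativity, x$clustering, x$k_shell))
  if (!is.na(x$n_c)) cat("  communities n_c =", x$n_c, "\n")
  invisible(x)
}
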