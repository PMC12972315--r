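# Target-oriented greedy edge rewiring under fixed N, M and connectivity.

# Registry of scalar objectives (all maximized) usable as rewiring targets
# and as recorded associated metrics.
objective_registry <- function() {
  list(
    pmi = function(g) pmi(g)$phi,
    community_number = function(g) detect_communities(g)$n_c,
    clustering = function(g) transitivity(g, type = "localaverage",
                                          isolates = "zero"),
    diameter = function(g) diameter(g),
    assortativity = function(g) assortativity_degree(g)
  )
}

get_objective <- function(name) {
  reg <- objective_registry()
  if (!name %in% names(reg)) {
    stop("unknown objective '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Propose one rewiring trial
#'
#' Applies `b` elementary rewirings to a connected graph. Each elementary
#' move deletes one uniformly chosen existing edge and adds one uniformly
#' chosen pair that was absent before the deletion, so node count and edge
#' count are preserved and no duplicate edge can arise. A move that
#' disconnects the graph is rejected and redrawn (up to `max_retries` times);
#' when no admissible move can be found (e.g. a complete graph has no absent
#' pair, or every deletion disconnects), the trial aborts with a condition of
#' class `pathmult_trial_abort` so the caller can redraw its budget.
#'
#' @param g a connected undirected simple igraph object.
#' @param b number of elementary rewirings, `1 <= b <= M`.
#' @param max_retries rejection budget per elementary move.
#' @return the rewired graph (same N and M, connected).
#' @export
propose_trial <- function(g, b, max_retries = 50L) {
  check_graph(g, connected = TRUE, min_nodes = 2L)
  m <- ecount(g)
  b <- as.integer(b)
  if (b < 1L || b > m) stop("`b` must be in [1, M]", call. = FALSE)
  n <- vcount(g)
  if (m == n * (n - 1) / 2) {
    abort_trial("complete graph: no absent edge to add")
  }
  for (step in seq_len(b)) {
    g <- elementary_rewire(g, max_retries)
  }
  g
}

abort_trial <- function(msg) {
  stop(structure(class = c("pathmult_trial_abort", "error", "condition"),
                 list(message = msg, call = NULL)))
}

elementary_rewire <- function(g, max_retries) {
  n <- vcount(g)
  for (try in seq_len(max_retries)) {
    eid <- sample.int(ecount(g), 1L)
    newpair <- sample_absent_pair(g)
    g2 <- add_edges(delete_edges(g, eid), newpair)
    if (is_connected(g2)) return(g2)
  }
  abort_trial("no admissible rewiring found within the retry budget")
}

# Uniformly sample a non-adjacent vertex pair; rejection sampling with an
# exact enumeration fallback for very dense graphs.
sample_absent_pair <- function(g, max_tries = 200L) {
  n <- vcount(g)
  for (try in seq_len(max_tries)) {
    pair <- sample.int(n, 2L)
    if (!are_adjacent(g, pair[1L], pair[2L])) return(pair)
  }
  A <- as.matrix(as_adjacency_matrix(g, type = "both", sparse = TRUE))
  absent <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  if (nrow(absent) == 0L) abort_trial("no absent edge to add")
  absent[sample.int(nrow(absent), 1L), ]
}

#' Select the best trial under a target objective
#'
#' Evaluates the objective on each trial graph, identifies the argmax set,
#' and returns one of its members uniformly at random. When every trial
#' scores strictly below `current_value`, the current state is retained
#' (`NULL` is returned), so accepted target series are non-decreasing; ties
#' with the current value are genuine candidates and may be accepted. Trials
#' whose evaluation fails are dropped with a message.
#'
#' @param trials list of candidate graphs.
#' @param f objective function `graph -> numeric`, or a registered objective
#'   name (see [optimize_rewiring()]).
#' @param current_value value of the currently accepted network (`-Inf` for
#'   the first iteration).
#' @return list with `graph` (or `NULL` if the current state is retained),
#'   `value`, and `n_tied`.
#' @export
select_best <- function(trials, f, current_value = -Inf) {
  if (is.character(f)) f <- get_objective(f)
  vals <- vapply(trials, function(tg) {
    tryCatch(as.numeric(f(tg)), error = function(e) {
      message("dropping trial: ", conditionMessage(e))
      NA_real_
    })
  }, 0)
  ok <- which(!is.na(vals))
  if (length(ok) == 0L) stop("no evaluable trial", call. = FALSE)
  best <- max(vals[ok])
  if (best < current_value) {
    return(list(graph = NULL, value = current_value, n_tied = 0L))
  }
  tied <- ok[vals[ok] == best]
  list(graph = trials[[pick_one(tied)]], value = best, n_tied = length(tied))
}

#' Greedy target-oriented rewiring optimization
#'
#' Iteratively improves a scalar graph objective by constrained random
#' rewiring: at each iteration `trials` candidate graphs are generated with
#' [propose_trial()] (each with a fresh uniform budget `b` in
#' `[1, b_max]`), the best candidate under the target objective is selected
#' with [select_best()], and the accepted state plus any associated metrics
#' are recorded. Node count, edge count and connectivity are preserved
#' throughout. The first recorded iteration is the best initial trial, not
#' the seed graph. Fully reproducible given `seed`.
#'
#' @param g0 a connected undirected simple igraph seed graph.
#' @param target objective to maximize: one of `"pmi"`,
#'   `"community_number"`, `"clustering"`, `"diameter"`, `"assortativity"`.
#' @param record character vector of associated metrics (same registry) to
#'   evaluate on each accepted state.
#' @param iterations number of recorded iterations.
#' @param trials candidate trials per iteration.
#' @param b_max maximum rewiring budget per trial (default `max(1, M/10)`).
#' @param seed integer seed.
#' @return object of class `rewiring_trajectory`: list with `trajectory`
#'   (data frame: `iteration`, `target`, one column per recorded metric,
#'   `accepted`), `final_graph`, `target_name`, `seed`.
#' @export
optimize_rewiring <- function(g0, target = "pmi", record = character(),
                              iterations = 50L, trials = 20L, b_max = NULL,
                              seed = 1L) {
  check_graph(g0, connected = TRUE, min_nodes = 2L)
  if (iterations < 1L || trials < 1L) {
    stop("`iterations` and `trials` must be >= 1", call. = FALSE)
  }
  f <- get_objective(target)
  rec_fns <- lapply(record, get_objective)
  names(rec_fns) <- record
  m <- ecount(g0)
  if (is.null(b_max)) b_max <- max(1L, m %/% 10L)
  b_max <- min(as.integer(b_max), m)

  with_seed(seed, {
    current <- g0
    current_val <- -Inf
    rows <- vector("list", iterations)
    for (it in seq_len(iterations)) {
      cand <- vector("list", trials)
      q <- 1L
      guard <- 0L
      while (q <= trials) {
        guard <- guard + 1L
        if (guard > 20L * trials) {
          stop("could not generate admissible rewiring trials", call. = FALSE)
        }
        b <- sample.int(b_max, 1L)
        tg <- tryCatch(propose_trial(current, b),
                       pathmult_trial_abort = function(e) NULL)
        if (!is.null(tg)) {
          cand[[q]] <- tg
          q <- q + 1L
        }
      }
      sel <- select_best(cand, f, current_val)
      accepted <- !is.null(sel$graph)
      if (accepted) {
        current <- sel$graph
        current_val <- sel$value
      }
      assoc <- vapply(rec_fns, function(fn) as.numeric(fn(current)), 0)
      rows[[it]] <- c(iteration = it, target = current_val, assoc,
                      accepted = as.numeric(accepted))
    }
    traj <- as.data.frame(do.call(rbind, rows))
    structure(
      list(trajectory = traj, final_graph = current, target_name = target,
           seed = seed),
      class = "rewiring_trajectory"
    )
  })
}

#' @exportS3Method base::print
print.rewiring_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat("Rewiring trajectory: target =", x$target_name,
      " iterations =", nrow(tr), "\n")
  cat("  target value:", format(tr$target[1L], digits = 6), "->",
      format(tr$target[nrow(tr)], digits = 6), "\n")
  invisible(x)
}

#' @exportS3Method base::plot
plot.rewiring_trajectory <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr$iteration, tr$target, type = "l",
                 xlab = "iteration", ylab = x$target_name, ...)
  invisible(x)
}
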