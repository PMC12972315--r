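# Experiment drivers: density sweeps, corpus summaries, rewiring ensembles
# and model comparisons.

#' PMI as a function of edge density across models
#'
#' For every combination of model, size, target density and seed: generate
#' the graph, reduce to the giant component, and compute the PMI. Chains and
#' complete graphs bound the sweep at Phi = 1 on both ends; in between the
#' relationship is non-monotone. Infeasible combinations (e.g. a ring
#' lattice that cannot realize the requested density) are skipped with a
#' message.
#'
#' @param models subset of `c("er", "rrl", "cba", "nw", "ba")`.
#' @param sizes integer vector of node counts.
#' @param densities numeric vector of target edge densities in (0, 1].
#' @param seeds integer vector of seeds (one run per seed).
#' @return data frame with columns `model`, `n`, `density_target`,
#'   `density_actual`, `seed`, `n_gc`, `phi`.
#' @export
run_pmi_vs_density <- function(models = c("er", "rrl", "cba"),
                               sizes = 100L,
                               densities = c(0.05, 0.1, 0.2, 0.4, 0.8, 1),
                               seeds = 1L) {
  rows <- list()
  for (model in models) for (n in sizes) for (p in densities) for (sd in seeds) {
    g <- tryCatch(generate_at_density(model, n, p, sd), error = function(e) {
      message("skipping ", model, " n=", n, " p=", p, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(g)) next
    gc <- giant_component(g)
    if (vcount(gc) < 2L) next
    rows[[length(rows) + 1L]] <- data.frame(
      model = model, n = n, density_target = p,
      density_actual = edge_density_frac(g), seed = sd,
      n_gc = vcount(gc), phi = pmi(gc)$phi
    )
  }
  do.call(rbind, rows)
}

generate_at_density <- function(model, n, p, seed) {
  m <- round(p * n * (n - 1) / 2)
  if (m < 1) stop("density too low")
  switch(model,
    er = er_graph(n, m = m, seed = seed),
    rrl = {
      k <- round(2 * m / n)
      k <- k + k %% 2
      rrl_graph(n, max(2L, k))
    },
    ba = ba_graph(n, max(1L, round(m / n)), seed = seed),
    cba = cba_graph(n, max(1L, round(m / n)), seed = seed),
    nw = {
      k <- max(2L, 2L * (m %/% (2L * n)))
      extra <- m - n * k / 2
      if (extra < 0) stop("density below the lattice floor")
      nw_graph(n, k, n_add = extra, seed = seed)
    },
    stop("unknown model '", model, "'")
  )
}

#' Corpus summary: metrics, PMI, RPMI and communities per network file
#'
#' Reads every graph file in a directory (edge list, `.mtx`, `.graphml`),
#' reduces each to its giant component, and tabulates the classical metrics
#' together with the PMI, the RPMI (seeded per network, derived from
#' `seed`), and the leading-eigenvector community count. With two or more
#' networks, each metric is then associated with the RPMI across the corpus
#' via Pearson, Spearman and QCR+. Unreadable files are skipped with a
#' message; a single-network corpus returns its row with the association
#' skipped.
#'
#' @param dir directory of graph files.
#' @param ensemble_size ER ensemble size for the RPMI.
#' @param seed integer base seed.
#' @param pattern optional filename regexp filter.
#' @return list with `table` (one row per network) and `association` (one
#'   row per metric: `metric`, `pearson`, `spearman`, `qcr_pos`; `NULL` when
#'   skipped).
#' @export
run_corpus <- function(dir, ensemble_size = 20L, seed = 1L, pattern = NULL) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("empty corpus: ", dir, call. = FALSE)
  rows <- list()
  for (fi in seq_along(files)) {
    row <- tryCatch(
      corpus_row(files[fi], ensemble_size, seed + fi),
      error = function(e) {
        message("skipping ", basename(files[fi]), ": ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("no readable network in corpus", call. = FALSE)
  tab <- do.call(rbind, rows)
  assoc <- NULL
  if (nrow(tab) >= 2L) {
    assoc <- corpus_association(tab)
  } else {
    message("single-network corpus: association skipped")
  }
  list(table = tab, association = assoc)
}

corpus_row <- function(path, ensemble_size, seed) {
  g <- giant_component(read_network(path))
  if (vcount(g) < 3L) stop("giant component too small")
  met <- classical_metrics(g)
  part <- detect_communities(g)
  rp <- rpmi(g, ensemble_size = ensemble_size, seed = seed)
  data.frame(
    network = basename(path), n = met$n, m = met$m, p = met$p,
    avg_degree = met$avg_degree, l_avg = met$l_avg, e_glob = met$e_glob,
    diameter = met$diameter, assortativity = met$assortativity,
    clustering = met$clustering, k_shell = met$k_shell,
    n_c = part$n_c, q_mod = part$Q,
    phi = rp$phi, phi_tilde = rp$phi_tilde,
    ensemble_size = rp$ensemble_size, seed = seed
  )
}

corpus_association <- function(tab) {
  metrics <- c("n_c", "avg_degree", "l_avg", "e_glob", "diameter",
               "assortativity", "clustering", "k_shell")
  rows <- list()
  n_fail <- 0L
  for (met in metrics) {
    row <- tryCatch(
      data.frame(metric = met,
                 pearson = pearson_r(tab[[met]], tab$phi_tilde),
                 spearman = spearman_rho(tab[[met]], tab$phi_tilde),
                 qcr_pos = qcr(tab[[met]], tab$phi_tilde, "positive")),
      error = function(e) {
        message("association for ", met, " undefined: ", conditionMessage(e))
        n_fail <<- n_fail + 1L
        NULL
      }
    )
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    stop("association undefined for every metric (no variation in corpus)",
         call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Rewiring trajectories over an ensemble of seed graphs
#'
#' Runs [optimize_rewiring()] from an independent connected ER seed graph
#' per seed and stacks the trajectories. Used to examine, at the ensemble
#' level, how an associated metric co-moves with the optimized target.
#'
#' @param n,m ER seed-graph size and edge count.
#' @param target,record,iterations,trials,b_max passed to
#'   [optimize_rewiring()].
#' @param seeds integer vector; one run per seed.
#' @return data frame: the per-run trajectories with a `seed` column.
#' @export
run_rewiring_experiment <- function(n = 30L, m = 60L, target = "pmi",
                                    record = "community_number",
                                    iterations = 50L, trials = 10L,
                                    b_max = NULL, seeds = 1:10) {
  rows <- lapply(seeds, function(sd) {
    g0 <- with_seed(sd, {
      for (try in 1:100) {
        g <- sample_gnm(n, m)
        if (is_connected(g)) break
      }
      if (!is_connected(g)) stop("could not draw a connected ER seed graph")
      g
    })
    tr <- optimize_rewiring(g0, target = target, record = record,
                            iterations = iterations, trials = trials,
                            b_max = b_max, seed = sd)
    cbind(seed = sd, tr$trajectory)
  })
  do.call(rbind, rows)
}

#' Compare PMA structure of a reference graph against matched models
#'
#' For the reference graph and each density-matched model graph, computes
#' the PMA histogram, the maximum PMA, and the PMI. The reference itself is
#' included as the first row, so a self-comparison is the identity.
#'
#' @param g_ref a connected reference graph.
#' @param models models to match (see [match_reference()]).
#' @param seed integer seed for the model draws.
#' @param model_params named list of per-model parameter lists (e.g.
#'   `list(tsf = list(n_c = 10, n_e = 2))`).
#' @return list with `summary` (data frame: `model`, `n`, `m`, `phi`,
#'   `max_pma`) and `histograms` (named list of [pma_histogram()] frames).
#' @export
run_model_comparison <- function(g_ref, models = c("tsf", "er", "nw", "ba"),
                                 seed = 1L, model_params = list()) {
  check_graph(g_ref, connected = TRUE, min_nodes = 3L)
  entries <- c(list(reference = g_ref),
               stats::setNames(lapply(seq_along(models), function(mi) {
                 do.call(match_reference,
                         c(list(g_ref = g_ref, model = models[mi],
                                seed = seed + mi),
                           model_params[[models[mi]]]))
               }), models))
  hists <- list()
  rows <- list()
  for (nm in names(entries)) {
    g <- giant_component(entries[[nm]])
    pm <- count_shortest_paths(g)
    n <- vcount(g)
    hists[[nm]] <- pma_histogram(pm)
    rows[[nm]] <- data.frame(
      model = nm, n = n, m = ecount(g),
      phi = sum(pm$H) / (n * (n - 1)), max_pma = max(pm$H)
    )
  }
  list(summary = do.call(rbind, rows), histograms = hists)
}
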