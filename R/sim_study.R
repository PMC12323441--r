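#' Define a simulation scenario
#'
#' A scenario fixes everything needed to draw replicate family datasets
#' and run one edge-testing method on them: the ground-truth graph, the
#' number of families `M` (mixed pedigree of [build_families()]), the
#' heritability, the method, and the bootstrap settings.
#'
#' @param graph a [graph_spec].
#' @param M number of families (even, at least 2).
#' @param h2 heritability in \[0, 1).
#' @param method `"cluster_boot"` (the cluster bootstrap),
#'   `"naive_boot"` (individual-level bootstrap ignoring clusters), or
#'   `"fisher"` (iid-theory Fisher Z test).
#' @param T,c bootstrap resample count and cluster percentage (ignored
#'   for `"fisher"`).
#' @param alpha nominal per-edge significance level.
#' @return An object of class `ggm_scenario`.
#' @export
scenario <- function(graph, M, h2,
                     method = c("cluster_boot", "naive_boot", "fisher"),
                     T = 50L, c = 100, alpha = 0.05) {
  stopifnot(inherits(graph, "graph_spec"))
  method <- match.arg(method)
  ped <- build_families(M)
  structure(list(graph = graph, M = as.integer(M), h2 = h2,
                 method = method, T = as.integer(T), c = c,
                 alpha = alpha, ped = ped,
                 model = trait_model(graph, h2)),
            class = "ggm_scenario")
}

#' @export
print.ggm_scenario <- function(x, ...) {
  cat(sprintf("scenario: %d-vertex graph, M = %d (N = %d), h2 = %g, %s\n",
              x$graph$p, x$M, x$ped$n, x$h2, x$method))
  invisible(x)
}

## p-values for every variable pair over `replicates` simulated
## datasets: one row per replicate, columns in all_pairs() order.  Each
## replicate gets its own simulation and bootstrap substream so results
## are reproducible replicate by replicate.
replicate_pvalues <- function(scn, replicates, seed) {
  stopifnot(inherits(scn, "ggm_scenario"))
  seeds <- matrix(spawn_seeds(seed, 2L * replicates), ncol = 2)
  n_pairs <- nrow(all_pairs(scn$graph$p))
  pv <- matrix(NA_real_, nrow = replicates, ncol = n_pairs)
  for (r in seq_len(replicates)) {
    dat <- simulate_traits(scn$model, scn$ped, seed = seeds[r, 1])
    edges <- tryCatch(
      switch(scn$method,
             fisher = iid_edge_test(dat, alpha = scn$alpha),
             naive_boot = bootstrap_edge_test(
               dat, bootstrap_config(T = scn$T, c = scn$c,
                                     mode = "individual",
                                     seed = seeds[r, 2],
                                     alpha = scn$alpha))$edges,
             cluster_boot = bootstrap_edge_test(
               dat, bootstrap_config(T = scn$T, c = scn$c,
                                     mode = "cluster",
                                     seed = seeds[r, 2],
                                     alpha = scn$alpha))$edges),
      error = function(e) {
        stop("replicate ", r, " failed: ", conditionMessage(e),
             call. = FALSE)
      })
    pv[r, ] <- edges$p_value
  }
  pv
}

## Split pair columns into null (no edge) and true-edge sets.
pair_truth <- function(graph) {
  pairs <- all_pairs(graph$p)
  on_edge <- abs(graph$partial_corr[pairs]) > 1e-10
  list(pairs = pairs, null = which(!on_edge), true = which(on_edge))
}

rejection_summary <- function(pv, cols, level, pairs) {
  prop <- colMeans(pv[, cols, drop = FALSE] < level)
  reps <- nrow(pv)
  data.frame(i = pairs[cols, 1], j = pairs[cols, 2],
             proportion = prop,
             se = sqrt(prop * (1 - prop) / reps),
             replicates = reps)
}

#' Estimate the false positive rate of a scenario
#'
#' Simulates `replicates` datasets, runs the scenario's method on each,
#' and reports the rejection proportion for every conditionally
#' independent pair (pairs without an edge in the ground-truth graph),
#' with binomial standard errors.
#'
#' @param scn a [scenario()] whose graph has at least one null pair.
#' @param replicates number of replicate datasets (>= 50 recommended).
#' @param alpha level at which rejection is assessed (defaults to the
#'   scenario's nominal level).
#' @param seed master seed; replicates use independent substreams.
#' @return A list of class `fpr_estimate`: `per_pair` (data frame with
#'   `i`, `j`, `proportion`, `se`), `mean_fpr`, `mean_inflation`
#'   (`mean_fpr / alpha`), `alpha`, and `replicates`.
#' @export
estimate_fpr <- function(scn, replicates = 1000, alpha = scn$alpha,
                         seed = 1L) {
  truth <- pair_truth(scn$graph)
  if (length(truth$null) < 1) {
    stop("scenario graph has no conditionally independent pair",
         call. = FALSE)
  }
  pv <- replicate_pvalues(scn, replicates, seed)
  per_pair <- rejection_summary(pv, truth$null, alpha, truth$pairs)
  structure(list(per_pair = per_pair,
                 mean_fpr = mean(per_pair$proportion),
                 mean_inflation = mean(per_pair$proportion) / alpha,
                 alpha = alpha, replicates = replicates),
            class = "fpr_estimate")
}

#' Estimate power for the true edges of a scenario
#'
#' As [estimate_fpr()], but reports rejection proportions for the pairs
#' that carry an edge in the ground-truth graph, assessed at an
#' operative level `alpha_star` (typically the output of
#' [adjust_alpha()], so that methods with inflated type I error are
#' compared fairly).
#'
#' @inheritParams estimate_fpr
#' @param alpha_star operative significance level.
#' @return A list of class `power_estimate`: `per_pair`, `min_power`,
#'   `mean_power`, `alpha_star`, `replicates`.
#' @export
estimate_power <- function(scn, replicates = 1000, alpha_star = scn$alpha,
                           seed = 1L) {
  truth <- pair_truth(scn$graph)
  if (length(truth$true) < 1) {
    stop("scenario graph has no true edge", call. = FALSE)
  }
  pv <- replicate_pvalues(scn, replicates, seed)
  per_pair <- rejection_summary(pv, truth$true, alpha_star, truth$pairs)
  structure(list(per_pair = per_pair,
                 min_power = min(per_pair$proportion),
                 mean_power = mean(per_pair$proportion),
                 alpha_star = alpha_star, replicates = replicates),
            class = "power_estimate")
}

## One update of the significance level by the measured inflation:
## alpha_next = nominal / (mean FPR at `current` / `current`).
next_alpha <- function(nominal, mean_fpr, current) {
  min(1, nominal * current / mean_fpr)
}

#' Iteratively adjust the significance level to the nominal FPR
#'
#' When a method's empirical false positive rate is inflated, power
#' comparisons at the nominal level are unfair.  This procedure
#' rescales the operative level by the measured mean inflation rate,
#' \eqn{\alpha^* = 0.05 / (\overline{FPR} / \alpha)} with
#' \eqn{\overline{FPR}} the null-pair rejection rate averaged over
#' pairs and measured at the current operative level \eqn{\alpha}, and
#' repeats (with a fresh replicate stream each round) until the
#' empirical mean FPR is within `tol` of the nominal level or
#' `max_iter` is reached.  If the FPR ever estimates to exactly zero
#' the level is capped at 1 with a warning, since no finite inflation
#' can be measured.
#'
#' @inheritParams estimate_fpr
#' @param nominal_alpha target false positive rate (default 0.05).
#' @param tol convergence tolerance on `|mean FPR - nominal|`; should
#'   not be much smaller than the binomial Monte Carlo error
#'   `sqrt(nominal * (1 - nominal) / replicates)`.
#' @param max_iter iteration cap; on non-convergence the level whose
#'   measured FPR was closest to nominal is returned, flagged.
#' @return A list of class `alpha_adjustment`: `alpha_star`, `trace`
#'   (data frame of `level` and `mean_fpr` per iteration, starting at
#'   the nominal level), and `converged`.
#' @export
adjust_alpha <- function(scn, replicates = 1000, nominal_alpha = 0.05,
                         tol = 0.005, max_iter = 10, seed = 1L) {
  if (nominal_alpha <= 0 || nominal_alpha >= 1) {
    stop("`nominal_alpha` must lie in (0, 1)", call. = FALSE)
  }
  seeds <- spawn_seeds(seed, max_iter)
  level <- nominal_alpha
  trace <- data.frame(level = numeric(0), mean_fpr = numeric(0))
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    fpr <- estimate_fpr(scn, replicates, alpha = level, seed = seeds[k])
    trace <- rbind(trace,
                   data.frame(level = level, mean_fpr = fpr$mean_fpr))
    if (abs(fpr$mean_fpr - nominal_alpha) <= tol) {
      converged <- TRUE
      break
    }
    if (fpr$mean_fpr == 0) {
      warning("mean FPR estimated as 0; operative level capped at 1")
      level <- 1
      next
    }
    level <- next_alpha(nominal_alpha, fpr$mean_fpr, level)
  }
  if (!converged) {
    best <- which.min(abs(trace$mean_fpr - nominal_alpha))
    level <- trace$level[best]
  }
  structure(list(alpha_star = level, trace = trace, converged = converged),
            class = "alpha_adjustment")
}

#' Run a grid of simulation scenarios
#'
#' Sweeps graphs x family counts x heritabilities x methods.  For each
#' cell the false positive rate is estimated at the nominal level; if
#' the graph has true edges the operative level is adjusted with
#' [adjust_alpha()] and power is estimated at the adjusted level.
#' Individual cell failures are recorded and the sweep continues.
#'
#' @param config a list (or YAML file read with [read_grid_config()])
#'   with elements `graphs` (named list of [graph_spec]s or character
#'   vector of [canonical_graph()] names), `M_values`, `methods`,
#'   `replicates`, and optionally `h2_values` (default grid 0, 0.125,
#'   0.25, 0.5, 0.75, 0.95), `T`, `c`, `alpha`, `adjust_replicates`,
#'   `tol`, `max_iter`, `seed`, `out_dir`.
#' @return A data frame of class `grid_result` with one row per
#'   (cell, pair): scenario columns, `pair_type` (`"null"`/`"true"`),
#'   rejection `proportion`, `se`, the operative `level`, `alpha_star`,
#'   and `mean_inflation` of the cell.  Per-cell errors (if any) are in
#'   `attr(, "failures")`.  When `out_dir` is given, the table is also
#'   written incrementally to `grid_results.tsv` there, and a JSON
#'   summary to `grid_summary.json`.
#' @export
run_grid <- function(config) {
  graphs <- config$graphs
  if (is.character(graphs)) {
    graphs <- stats::setNames(lapply(graphs, canonical_graph), graphs)
  }
  stopifnot(length(graphs) >= 1, !is.null(names(graphs)))
  reps <- config$replicates %||% 1000
  adj_reps <- config$adjust_replicates %||% reps
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  cells <- expand.grid(graph = names(graphs),
                       M = config$M_values,
                       h2 = config$h2_values %||%
                         c(0, 0.125, 0.25, 0.5, 0.75, 0.95),
                       method = config$methods,
                       stringsAsFactors = FALSE)
  cell_seeds <- matrix(spawn_seeds(seed, 3L * nrow(cells)), ncol = 3)
  rows <- list()
  failures <- list()
  out_path <- if (!is.null(out_dir)) file.path(out_dir, "grid_results.tsv")
  if (!is.null(out_path) && file.exists(out_path)) file.remove(out_path)
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    res <- tryCatch({
      g <- graphs[[cell$graph]]
      scn <- scenario(g, M = cell$M, h2 = cell$h2, method = cell$method,
                      T = config$T %||% 50L, c = config$c %||% 100,
                      alpha = alpha)
      truth <- pair_truth(g)
      out <- NULL
      alpha_star <- alpha
      infl <- NA_real_
      if (length(truth$null) > 0) {
        fpr <- estimate_fpr(scn, reps, alpha = alpha,
                            seed = cell_seeds[k, 1])
        infl <- fpr$mean_inflation
        out <- cbind(fpr$per_pair, pair_type = "null", level = alpha)
      }
      if (length(truth$true) > 0) {
        adj <- if (length(truth$null) > 0) {
          adjust_alpha(scn, adj_reps, nominal_alpha = alpha,
                       tol = config$tol %||% 0.005,
                       max_iter = config$max_iter %||% 10,
                       seed = cell_seeds[k, 2])
        } else list(alpha_star = alpha)
        alpha_star <- adj$alpha_star
        pow <- estimate_power(scn, reps, alpha_star = alpha_star,
                              seed = cell_seeds[k, 3])
        out <- rbind(out, cbind(pow$per_pair, pair_type = "true",
                                level = alpha_star))
      }
      cbind(graph = cell$graph, M = cell$M, h2 = cell$h2,
            method = cell$method, out,
            alpha_star = alpha_star, mean_inflation = infl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(graph = cell$graph, M = cell$M, h2 = cell$h2,
                   method = cell$method, message = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- res
    if (!is.null(out_dir)) {
      utils::write.table(res, out_path, sep = "\t", quote = FALSE,
                         row.names = FALSE,
                         col.names = !file.exists(out_path),
                         append = file.exists(out_path))
    }
  }
  result <- do.call(rbind, rows)
  attr(result, "failures") <- if (length(failures)) do.call(rbind, failures)
  class(result) <- c("grid_result", "data.frame")
  if (!is.null(out_dir)) {
    summary <- list(cells = nrow(cells), failed = length(failures),
                    replicates = reps, alpha = alpha, seed = seed)
    jsonlite::write_json(summary, file.path(out_dir, "grid_summary.json"),
                         auto_unbox = TRUE)
  }
  result
}

#' Read a grid configuration from YAML or JSON
#'
#' @param path configuration file; top-level keys as in [run_grid()].
#' @return A config list suitable for [run_grid()].
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("graphs", "M_values", "methods")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("grid config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg
}
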