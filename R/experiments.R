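#' Configuration for a simulation scenario
#'
#' Bundles the micro-level rates, duration, replicate count and master seed
#' of one scenario. Replicate r always uses a private seed derived
#' deterministically from `(seed, r)`, so runs are reproducible and
#' individual replicates can be regenerated in isolation.
#'
#' @param label Scenario name used in reports.
#' @param splitting_rate,conversion_rate,extirpation_rate Micro rates
#'   (lambda', chi, mu'), per Myr; the same splitting and extirpation rates
#'   are applied to good and incipient lineages.
#' @param duration Simulated time span, Myr; default 6.
#' @param n_reps Number of replicate genealogies; default 100.
#' @param seed Master seed (integer).
#' @return A `scenario_config` object.
#' @examples
#' scenario_config("temperate-1", 1.16, 0.5, 0.6, seed = 1)
#' @export
scenario_config <- function(label, splitting_rate, conversion_rate,
                            extirpation_rate, duration = 6, n_reps = 100L,
                            seed = 1L) {
  stopifnot(n_reps >= 1L)
  structure(list(label = label,
                 params = pbd_params(splitting_rate, conversion_rate,
                                     extirpation_rate, duration = duration),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Run one protracted-speciation scenario
#'
#' Simulates `n_reps` genealogies, prunes each to a species tree with one
#' random representative per species, and aggregates species richness and
#' sister-pair (cherry) cophenetic distances. Distances are pooled across
#' replicates; single-species replicates contribute richness 1 but no
#' distances.
#'
#' @param cfg A [scenario_config()].
#' @param keep_trees Keep the pruned species trees in the result (default
#'   TRUE; set FALSE to save memory in large sweeps).
#' @return A `scenario_summary` object: list with `label`, `replicates` (data
#'   frame: `rep`, `richness`, `n_extant_lineages`, `n_restarts`,
#'   `n_cherries`), `sister_distances` (pooled numeric vector),
#'   `mean_richness`, `se_richness`, `mean_distance`, `se_distance`,
#'   `trees` (list of `phylo` or NULL), and `config`.
#' @export
run_scenario <- function(cfg, keep_trees = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"))
  rows <- vector("list", cfg$n_reps)
  dists <- vector("list", cfg$n_reps)
  trees <- if (keep_trees) vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    g <- simulate_genealogy(cfg$params, seed = derive_seed(cfg$seed, r))
    tr <- sample_species_tree(g)            # continues the replicate stream
    nt <- length(tr$tip.label)
    d <- if (nt >= 2L) sister_distances(tr)$distance else numeric(0)
    rows[[r]] <- data.frame(
      rep = r, richness = extant_richness(g),
      n_extant_lineages = sum(g$lineages$fate == "extant"),
      n_restarts = g$n_restarts, n_cherries = length(d))
    dists[[r]] <- d
    if (keep_trees) trees[[r]] <- tr
  }
  reps <- do.call(rbind, rows)
  pooled <- unlist(dists)
  structure(list(
    label = cfg$label, replicates = reps, sister_distances = pooled,
    mean_richness = mean(reps$richness),
    se_richness = stats::sd(reps$richness) / sqrt(nrow(reps)),
    mean_distance = if (length(pooled)) mean(pooled) else NA_real_,
    se_distance = if (length(pooled) >= 2L)
      stats::sd(pooled) / sqrt(length(pooled)) else NA_real_,
    trees = trees, config = cfg), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d replicates, %g Myr):\n", x$label,
              nrow(x$replicates), x$config$params$duration))
  cat(sprintf("  mean species richness   %.2f +/- %.2f (SE)\n",
              x$mean_richness, x$se_richness))
  cat(sprintf("  mean sister distance    %.3f +/- %.3f (SE, %d pairs)\n",
              x$mean_distance, x$se_distance, length(x$sister_distances)))
  invisible(x)
}

#' Latitudinal-diversity-gradient experiment
#'
#' Runs the three bird diversification scenarios — tropical (lambda' = 1.13,
#' chi = 0.15, mu' = 0.3), temperate scenario 1 (1.16, 0.5, 0.6) and
#' temperate scenario 2 (1.3, 0.15, 0.6; tropical conversion rate with a
#' higher splitting rate) — for 6 Myr each, and compares them with Welch's
#' t-tests: species richness (tropical vs temperate-1) and pooled sister
#' cophenetic distances (tropical vs temperate-1, temperate-2 vs
#' temperate-1).
#'
#' @param n_reps Replicates per scenario; default 100.
#' @param duration Myr; default 6.
#' @param seed Master seed; scenario s, replicate r uses a seed derived from
#'   `(seed + s, r)`.
#' @param keep_trees Passed to [run_scenario()].
#' @return An `ldg_result`: list with `scenarios` (named list of
#'   `scenario_summary`) and `tests` (named list of [welch_t()] results:
#'   `richness_trop_vs_temp1`, `distance_trop_vs_temp1`,
#'   `distance_temp2_vs_temp1`).
#' @export
run_ldg_experiment <- function(n_reps = 100L, duration = 6, seed = 1L,
                               keep_trees = FALSE) {
  cfgs <- list(
    tropical = scenario_config("tropical", 1.13, 0.15, 0.3,
                               duration, n_reps, seed + 1L),
    temperate1 = scenario_config("temperate-1", 1.16, 0.5, 0.6,
                                 duration, n_reps, seed + 2L),
    temperate2 = scenario_config("temperate-2", 1.30, 0.15, 0.6,
                                 duration, n_reps, seed + 3L))
  sc <- lapply(cfgs, run_scenario, keep_trees = keep_trees)
  tests <- if (n_reps >= 2L) list(
    richness_trop_vs_temp1 = welch_t(sc$tropical$replicates$richness,
                                     sc$temperate1$replicates$richness),
    distance_trop_vs_temp1 = welch_t(sc$tropical$sister_distances,
                                     sc$temperate1$sister_distances),
    distance_temp2_vs_temp1 = welch_t(sc$temperate2$sister_distances,
                                      sc$temperate1$sister_distances))
  else NULL
  structure(list(scenarios = sc, tests = tests), class = "ldg_result")
}

#' @export
print.ldg_result <- function(x, ...) {
  for (s in x$scenarios) print(s)
  if (is.null(x$tests)) {
    cat("Welch tests: not available (fewer than 2 replicates)\n")
  } else {
    cat("Welch's t-tests:\n")
    for (nm in names(x$tests)) {
      tt <- x$tests[[nm]]
      cat(sprintf("  %-24s t = %8.3f, df = %8.1f, p = %.3g\n",
                  nm, tt$statistic, tt$df, tt$p_value))
    }
  }
  invisible(x)
}

#' Factorial sweep of the protracted parameter space with birth-death
#' re-estimation
#'
#' For every combination of the three micro rates, simulates `n_reps`
#' genealogies, prunes each to a species tree, fits the constant-rate
#' birth-death model by maximum likelihood to every tree with at least 2
#' tips, and records the per-cell means of the estimated speciation and
#' extinction rates. Defaults reproduce the published 5 x 5 x 5 design:
#' lambda' in 0.50-0.70, chi in 0.01-0.21, mu' in 0.25-0.45 (evenly spaced),
#' 15 Myr, 200 replicates per cell.
#'
#' @param splitting_values,conversion_values,extirpation_values Grid axes
#'   (per Myr).
#' @param n_reps Replicates per cell; default 200.
#' @param duration Myr; default 15.
#' @param seed Master seed; cell c, replicate r uses a seed derived from
#'   `(seed + c, r)`.
#' @return A `grid_result` data frame: one row per cell with
#'   `splitting_rate`, `conversion_rate`, `extirpation_rate`,
#'   `mean_lambda_hat`, `se_lambda_hat`, `mean_mu_hat`, `se_mu_hat`,
#'   `mean_n_tips`, `n_fits` (trees fitted, i.e. >= 2 tips and converged),
#'   `n_excluded` (single-tip or non-converged).
#' @export
run_grid_experiment <- function(splitting_values = seq(0.50, 0.70, by = 0.05),
                                conversion_values = seq(0.01, 0.21, by = 0.05),
                                extirpation_values = seq(0.25, 0.45, by = 0.05),
                                n_reps = 200L, duration = 15, seed = 1L) {
  cells <- expand.grid(splitting_rate = splitting_values,
                       conversion_rate = conversion_values,
                       extirpation_rate = extirpation_values,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    p <- pbd_params(cells$splitting_rate[ci], cells$conversion_rate[ci],
                    cells$extirpation_rate[ci], duration = duration)
    trees <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      g <- simulate_genealogy(p, seed = derive_seed(seed + ci, r))
      trees[[r]] <- sample_species_tree(g)
    }
    fits <- bd_fit_trees(trees)
    conv <- fits[fits$converged, , drop = FALSE]
    out[[ci]] <- data.frame(
      cells[ci, , drop = FALSE],
      mean_lambda_hat = mean(conv$lambda_hat),
      se_lambda_hat = stats::sd(conv$lambda_hat) / sqrt(nrow(conv)),
      mean_mu_hat = mean(conv$mu_hat),
      se_mu_hat = stats::sd(conv$mu_hat) / sqrt(nrow(conv)),
      mean_n_tips = mean(conv$n_tips),
      n_fits = nrow(conv),
      n_excluded = n_reps - nrow(conv))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("grid_result", "data.frame")
  res
}

#' Parameter combinations that yield indistinguishable estimated speciation
#' rates
#'
#' Enumerates pairs of grid cells whose mean estimated speciation rates agree
#' within `tolerance` although their micro-level parameters differ in at
#' least two of the three rates — the confounded combinations that make the
#' macro-level rate uninformative about the underlying process.
#'
#' @param grid A [run_grid_experiment()] result.
#' @param tolerance Absolute tolerance on the difference of mean estimated
#'   speciation rates; default 0.02 per Myr.
#' @return Data frame of cell pairs (`*_1`, `*_2` parameter columns,
#'   `mean_lambda_hat_1/2`, `delta_lambda_hat`, `n_axes_differ`,
#'   `param_distance`), sorted by decreasing Euclidean distance between the
#'   micro-parameter vectors.
#' @export
confounding_report <- function(grid, tolerance = 0.02) {
  stopifnot(inherits(grid, "data.frame"))
  n <- nrow(grid)
  if (n < 2L)
    return(data.frame())
  prs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- prs[, 1]; j <- prs[, 2]
  dl <- abs(grid$mean_lambda_hat[i] - grid$mean_lambda_hat[j])
  pm <- as.matrix(grid[, c("splitting_rate", "conversion_rate",
                           "extirpation_rate")])
  ndiff <- rowSums(abs(pm[i, , drop = FALSE] - pm[j, , drop = FALSE]) > 1e-12)
  keep <- !is.na(dl) & dl <= tolerance & ndiff >= 2L
  i <- i[keep]; j <- j[keep]
  dist <- sqrt(rowSums((pm[i, , drop = FALSE] - pm[j, , drop = FALSE])^2))
  out <- data.frame(
    splitting_rate_1 = pm[i, 1], conversion_rate_1 = pm[i, 2],
    extirpation_rate_1 = pm[i, 3],
    splitting_rate_2 = pm[j, 1], conversion_rate_2 = pm[j, 2],
    extirpation_rate_2 = pm[j, 3],
    mean_lambda_hat_1 = grid$mean_lambda_hat[i],
    mean_lambda_hat_2 = grid$mean_lambda_hat[j],
    delta_lambda_hat = abs(grid$mean_lambda_hat[i] - grid$mean_lambda_hat[j]),
    n_axes_differ = ndiff[keep],
    param_distance = dist)
  out[order(-out$param_distance), , drop = FALSE]
}
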