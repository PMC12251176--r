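#' Discover conformational states in an ensemble
#'
#' Stage 1+2 of the pipeline: compute theoretical curves for every model,
#' then run the confidence-threshold sweep with PCA and agglomerative
#' clustering, returning representatives per state.
#'
#' @param ensemble a [structure_ensemble()].
#' @param opts a [forward_options()].
#' @param base_cutoff lowest confidence cutoff for the sweep.
#' @param thresholds `"auto"` or explicit cutoffs (see [threshold_sweep()]).
#' @param k number of clusters.
#' @param silhouette_floor warn if the best silhouette falls below this
#'   (poor cluster separation).
#' @return list with `curves` (per-model list) and `sweep`
#'   (a [threshold_sweep()] result).
#' @export
run_state_discovery <- function(ensemble, opts = forward_options(),
                                base_cutoff = 75, thresholds = "auto",
                                k = 2L, silhouette_floor = 0.5) {
  curves <- batch_curves(ensemble, opts)
  sweep <- threshold_sweep(ensemble, curves, thresholds = thresholds,
                           base_cutoff = base_cutoff, k = k)
  if (sweep$best_silhouette < silhouette_floor)
    warning("best silhouette ", format(sweep$best_silhouette, digits = 3),
            " is below ", silhouette_floor,
            ": clusters are poorly separated", call. = FALSE)
  list(curves = curves, sweep = sweep)
}

#' Fit state populations for two conditions plus their difference
#'
#' Stage 3 of the pipeline: aligns condition B onto condition A's grid and
#' both state curves onto the common experimental grid, fits each condition
#' with a two-state mixture, averages the two best-fit scales, and fits the
#' between-condition difference curve for the population shift.
#'
#' @param I1,I2 theoretical state curves (state 1 and state 2).
#' @param exp_a,exp_b experimental curves (conditions A and B) with errors.
#' @param grid_step weight/shift grid step.
#' @return list of class `population_fit`: `fit_a`, `fit_b`
#'   ([two_state_fit()]), `f_bar`, `diff` ([difference_fit()]).
#' @export
run_population_fit <- function(I1, I2, exp_a, exp_b, grid_step = 0.01) {
  ab <- align_to_grid(exp_a, exp_b)
  exp_a <- ab$a; exp_b <- ab$b
  I1 <- align_to_grid(exp_a, I1)$b
  I2 <- align_to_grid(exp_a, I2)$b
  fit_a <- two_state_fit(I1, I2, exp_a, grid_step)
  fit_b <- two_state_fit(I1, I2, exp_b, grid_step)
  f_bar <- (fit_a$f + fit_b$f) / 2
  dfit <- difference_fit(I1, I2, exp_a, exp_b, f_bar, grid_step)
  structure(list(fit_a = fit_a, fit_b = fit_b, f_bar = f_bar, diff = dfit),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat("<population_fit>\n  condition A: "); print(x$fit_a)
  cat("  condition B: "); print(x$fit_b)
  cat(sprintf("  f_bar = %.4g\n  difference: ", x$f_bar)); print(x$diff)
  invisible(x)
}

#' @export
glance.population_fit <- function(x, ...) {
  tibble::tibble(w1_a = x$fit_a$w1, chi2_a = x$fit_a$chi2,
                 w1_b = x$fit_b$w1, chi2_b = x$fit_b$chi2,
                 f_bar = x$f_bar,
                 delta_w = x$diff$delta_w, chi2_delta = x$diff$chi2_delta)
}

#' Run the full pipeline on on-disk inputs
#'
#' Reads an ensemble directory and two experimental curve files, discovers
#' states, takes the per-cluster representatives' theoretical curves as the
#' state curves (state 1 = cluster with higher PC1, state 2 = lower), and
#' fits populations and the population shift.
#'
#' @param ensemble_dir directory of PDB/mmCIF models (confidence in
#'   B-factors).
#' @param exp_a_path,exp_b_path 3-column `.dat` experimental curves.
#' @param opts a [forward_options()].
#' @param base_cutoff lowest confidence cutoff for the sweep.
#' @param grid_step fit grid step.
#' @param pattern filename glob for the ensemble directory.
#' @return list of class `sans_run`: `ensemble`, `curves`, `sweep`,
#'   `state_curves`, `popfit`, `summary` (a plain list suitable for JSON).
#' @export
run_pipeline <- function(ensemble_dir, exp_a_path, exp_b_path,
                         opts = forward_options(), base_cutoff = 75,
                         grid_step = 0.01, pattern = "*.pdb") {
  ensemble <- read_ensemble(ensemble_dir, pattern = pattern)
  disc <- run_state_discovery(ensemble, opts, base_cutoff = base_cutoff)
  reps <- disc$sweep$representatives
  # state 1 = higher-PC1 cluster representative, state 2 = lower
  rep_hi <- reps$model_id[reps$label == max(reps$label)]
  rep_lo <- reps$model_id[reps$label == min(reps$label)]
  I1 <- disc$curves[[rep_hi]]
  I2 <- disc$curves[[rep_lo]]
  exp_a <- read_sans_curve(exp_a_path)
  exp_b <- read_sans_curve(exp_b_path)
  pf <- run_population_fit(I1, I2, exp_a, exp_b, grid_step)
  summary <- list(
    inputs = list(ensemble_dir = ensemble_dir, exp_a = exp_a_path,
                  exp_b = exp_b_path, n_models = length(ensemble$models)),
    settings = list(base_cutoff = base_cutoff, grid_step = grid_step,
                    q_points = length(opts$q_grid),
                    shell_enabled = opts$shell_enabled),
    best_threshold = disc$sweep$best_threshold,
    best_silhouette = disc$sweep$best_silhouette,
    n_retained = nrow(disc$sweep$labels),
    representatives = stats::setNames(as.list(reps$model_id),
                                      paste0("cluster_", reps$label)),
    w1_a = pf$fit_a$w1, chi2_a = pf$fit_a$chi2,
    w1_b = pf$fit_b$w1, chi2_b = pf$fit_b$chi2,
    f_bar = pf$f_bar,
    delta_w = pf$diff$delta_w, chi2_delta = pf$diff$chi2_delta)
  structure(list(ensemble = ensemble, curves = disc$curves,
                 sweep = disc$sweep,
                 state_curves = list(I1 = I1, I2 = I2),
                 popfit = pf, summary = summary),
            class = "sans_run")
}

#' @export
print.sans_run <- function(x, ...) {
  cat("<sans_run>\n")
  print(x$sweep)
  print(x$popfit)
  invisible(x)
}

#' Write a machine-readable run summary
#'
#' @param run a `sans_run` (or any list with a `summary` element, or a plain
#'   list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(run, path) {
  s <- if (!is.null(run$summary)) run$summary else run
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
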