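# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic two-state fixture
#'
#' Describes a planted ground truth the pipeline should recover: two bead
#' "states" built from stacked rings whose radius differs between states
#' (mimicking pore expansion between closed-like and open-like channel
#' conformations), low-confidence geometric intermediates, and noisy
#' weighted-mixture "experimental" curves for two conditions.
#'
#' Defaults: ring radii 5 and 6.5 Angstrom, 20 models per state with 0.15
#' Angstrom coordinate jitter, 6 intermediates, planted per-model confidence
#' uniform on 85-90 for states and 76-80 for intermediates, 1% relative curve
#' noise, condition weights (1, 0) and (0.7, 0.3) — a 0.30 population shift —
#' and unit scale.
#'
#' @param ring_radii length-2 radii (Angstrom) of the two states' rings.
#' @param n_models_per_state models per state.
#' @param n_intermediates geometric intermediates with low confidence.
#' @param n_rings,beads_per_ring,ring_spacing bead-model topology: stacked
#'   rings along z.
#' @param jitter_sd per-coordinate Gaussian jitter (Angstrom).
#' @param confidence_state,confidence_intermediate uniform confidence ranges.
#' @param noise_sd_relative relative noise level of experimental curves.
#' @param true_weights list of per-condition state weights, each summing to 1.
#' @param true_scale scale factor applied to the mixtures.
#' @param seed integer seed; all fixture randomness flows from it.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(ring_radii = c(5, 6.5),
                         n_models_per_state = 20,
                         n_intermediates = 6,
                         n_rings = 5, beads_per_ring = 12, ring_spacing = 3,
                         jitter_sd = 0.15,
                         confidence_state = c(85, 90),
                         confidence_intermediate = c(76, 80),
                         noise_sd_relative = 0.01,
                         true_weights = list(resting = c(1, 0),
                                             activating = c(0.7, 0.3)),
                         true_scale = 1,
                         seed = 1L) {
  stopifnot(length(ring_radii) == 2L, all(ring_radii > 0),
            noise_sd_relative >= 0, true_scale > 0)
  for (w in true_weights) {
    if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-12)
      stop("condition weights must lie in [0,1] and sum to 1", call. = FALSE)
  }
  if (ring_radii[1] == ring_radii[2])
    warning("equal state radii: states are degenerate", call. = FALSE)
  structure(as.list(environment()), class = "fixture_spec")
}

# stacked-ring bead model; radius interpolates between states for u in [0,1]
ring_bead_atoms <- function(spec, radius, jitter = TRUE) {
  k <- seq_len(spec$n_rings)
  z0 <- (k - (spec$n_rings + 1) / 2) * spec$ring_spacing
  ang <- 2 * pi * (seq_len(spec$beads_per_ring) - 1) / spec$beads_per_ring
  g <- expand.grid(a = ang, z = z0)
  x <- radius * cos(g$a); y <- radius * sin(g$a); z <- g$z
  n <- length(x)
  if (jitter && spec$jitter_sd > 0) {
    x <- x + stats::rnorm(n, 0, spec$jitter_sd)
    y <- y + stats::rnorm(n, 0, spec$jitter_sd)
    z <- z + stats::rnorm(n, 0, spec$jitter_sd)
  }
  tibble::tibble(element = "C", atom_name = "CA", res_name = "ALA",
                 res_id = seq_len(n), chain = "A",
                 x = x, y = y, z = z, confidence = 0)
}

set_confidence <- function(atoms, value) {
  atoms$confidence <- value
  atoms
}

#' Generate a two-state bead ensemble with planted ground truth
#'
#' State 1 and state 2 are stacked-ring bead models at the two ring radii;
#' intermediates interpolate the radius and receive lower planted confidence,
#' emulating ensembles where partially formed conformations score poorly.
#' All randomness flows from `spec$seed`; identical specs give identical
#' output.
#'
#' @param spec a [fixture_spec()].
#' @return list with `ensemble` (a [structure_ensemble()]), `truth` (tibble
#'   `model_id`, `state` in `{"state1","state2","intermediate"}`,
#'   `mix_fraction`, `confidence`) and `ideal_states` (list of the two
#'   jitter-free [structure_model()]s).
#' @export
make_two_state_ensemble <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    n_state <- spec$n_models_per_state
    plan <- tibble::tibble(
      state = c(rep("state1", n_state), rep("state2", n_state),
                rep("intermediate", spec$n_intermediates)),
      mix_fraction = c(rep(0, n_state), rep(1, n_state),
                       if (spec$n_intermediates > 0)
                         seq_len(spec$n_intermediates) / (spec$n_intermediates + 1)
                       else numeric(0)))
    n <- nrow(plan)
    plan$model_id <- sprintf("model_%03d", seq_len(n))
    plan$confidence <- ifelse(
      plan$state == "intermediate",
      stats::runif(n, spec$confidence_intermediate[1], spec$confidence_intermediate[2]),
      stats::runif(n, spec$confidence_state[1], spec$confidence_state[2]))
    models <- lapply(seq_len(n), function(i) {
      r <- spec$ring_radii[1] +
        plan$mix_fraction[i] * diff(spec$ring_radii)
      atoms <- set_confidence(ring_bead_atoms(spec, r), plan$confidence[i])
      structure_model(plan$model_id[i], atoms)
    })
    ideal <- list(
      state1 = structure_model("ideal_state1",
        set_confidence(ring_bead_atoms(spec, spec$ring_radii[1], jitter = FALSE), 100)),
      state2 = structure_model("ideal_state2",
        set_confidence(ring_bead_atoms(spec, spec$ring_radii[2], jitter = FALSE), 100)))
    list(ensemble = structure_ensemble(models,
                                       provenance = list(generator = "fixture",
                                                         seed = spec$seed)),
         truth = plan[, c("model_id", "state", "mix_fraction", "confidence")],
         ideal_states = ideal)
  })
}

#' Simulate an experimental curve from a weighted state mixture
#'
#' `I_exp = f * sum_s w_s I_s + eps` with independent Gaussian noise per
#' point. The per-point noise SD is `noise_sd_relative` times the noiseless
#' intensity, floored at 5% of its maximum so the error column never
#' collapses near intensity minima; the reported `sigma` equals the
#' generating SD.
#'
#' @param state_curves list of theoretical state [sans_curve()]s on a common
#'   grid.
#' @param weights state weights summing to 1.
#' @param f scale factor (> 0).
#' @param noise_sd_relative relative noise level (>= 0); with 0 the curve is
#'   exact and `sigma` is set to 1% of the mean intensity so chi-square
#'   weighting stays defined.
#' @param seed optional integer seed.
#' @param label curve label.
#' @return a [sans_curve()] with errors.
#' @export
make_experiment <- function(state_curves, weights, f = 1,
                            noise_sd_relative = 0.01, seed = NULL,
                            label = "synthetic experiment") {
  stopifnot(length(state_curves) == length(weights), f > 0)
  if (noise_sd_relative < 0) stop("negative noise level", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1", call. = FALSE)
  q <- state_curves[[1]]$q
  I0 <- f * Reduce(`+`, purrr::map2(state_curves, weights, function(cv, w) {
    if (!same_grid(cv, state_curves[[1]]))
      stop("state curves are not on a common grid", call. = FALSE)
    w * cv$I
  }))
  if (noise_sd_relative > 0) {
    sd_pt <- noise_sd_relative * pmax(abs(I0), 0.05 * max(abs(I0)))
    eps <- if (is.null(seed)) stats::rnorm(length(q), 0, sd_pt)
    else with_local_seed(seed, stats::rnorm(length(q), 0, sd_pt))
    sans_curve(q, I0 + eps, sd_pt, label = label)
  } else {
    sans_curve(q, I0, rep(0.01 * mean(abs(I0)), length(q)), label = label)
  }
}

#' Write a fixture to disk in pipeline-consumable formats
#'
#' Writes one PDB per model (confidence in the B-factor column), the truth
#' table as TSV, and the two conditions' synthetic experimental curves as
#' 3-column `.dat` files, so the directory is a valid input to the real
#' pipeline.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param opts [forward_options()] used for the planted state curves;
#'   defaults to shell-free bead settings.
#' @return invisibly, the list from [make_two_state_ensemble()] plus
#'   `experiments` (list of condition curves) and `dir`.
#' @export
write_fixture <- function(spec, dir,
                          opts = forward_options(shell_enabled = FALSE)) {
  fx <- make_two_state_ensemble(spec)
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  for (m in fx$ensemble$models)
    write_structure_pdb(m, file.path(dir, "models", paste0(m$model_id, ".pdb")))
  utils::write.table(fx$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  state_curves <- lapply(fx$ideal_states, debye_intensity, opts = opts)
  exps <- purrr::imap(spec$true_weights, function(w, nm) {
    make_experiment(state_curves, w, f = spec$true_scale,
                    noise_sd_relative = spec$noise_sd_relative,
                    seed = spec$seed + match(nm, names(spec$true_weights)),
                    label = nm)
  })
  for (nm in names(exps))
    write_sans_curve(exps[[nm]], file.path(dir, paste0(nm, ".dat")))
  invisible(c(fx, list(experiments = exps, dir = dir)))
}
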