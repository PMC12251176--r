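# Coherent neutron scattering lengths (fm) and displaced solvent volumes (A^3)
neutron_b_coh <- c(H = -3.7406, D = 6.671, C = 6.6511, N = 9.37, O = 5.803,
                   S = 2.847, P = 5.13)
displaced_volume <- c(H = 5.15, D = 5.15, C = 16.44, N = 2.49, O = 9.13,
                      S = 19.86, P = 5.73)
# solvent scattering-length density, fm/A^3, linear in D2O fraction
sld_h2o <- -0.0560
sld_d2o <- 0.6360

vdw_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)

solvent_sld <- function(d2o_fraction) {
  sld_h2o + d2o_fraction * (sld_d2o - sld_h2o)
}

#' Forward-model options
#'
#' Settings for the implicit-solvent Debye-sum SANS/SAXS calculator. Defaults
#' mirror a 100% D2O buffer with no protein deuteration, a 5.50898% hydration
#' shell contrast, solvent-displacement radius ratio r0/rm = 1 and curves
#' normalized to I(0) = 1.
#'
#' @param q_grid scattering-vector grid (1/Angstrom), non-negative increasing;
#'   default 201 uniform points on [0, 0.45].
#' @param buffer_d2o_fraction D2O fraction of the buffer in [0, 1].
#' @param protein_deuteration_fraction non-exchangeable H replaced by D, [0, 1].
#' @param hydration_contrast_percent hydration-shell contrast as percent of the
#'   solvent scattering-length density.
#' @param shell_enabled add a hydration-shell bead layer.
#' @param probe_radius_ratio ratio r0/rm scaling displaced atomic volumes.
#' @param mode `"atomic"` (one site per atom) or `"residue-bead"` (per-residue
#'   scattering lengths summed and placed at the Calpha).
#' @param normalize_I0 scale curves so I(0) = 1.
#' @param strict_elements error on unknown elements instead of falling back to
#'   carbon with a warning.
#' @return a list of class `forward_options`.
#' @export
forward_options <- function(q_grid = seq(0, 0.45, length.out = 201),
                            buffer_d2o_fraction = 1.0,
                            protein_deuteration_fraction = 0.0,
                            hydration_contrast_percent = 5.50898,
                            shell_enabled = TRUE,
                            probe_radius_ratio = 1.0,
                            mode = c("atomic", "residue-bead"),
                            normalize_I0 = TRUE,
                            strict_elements = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(q_grid) >= 2L, all(q_grid >= 0), all(diff(q_grid) > 0),
            buffer_d2o_fraction >= 0, buffer_d2o_fraction <= 1,
            protein_deuteration_fraction >= 0, protein_deuteration_fraction <= 1,
            probe_radius_ratio > 0)
  structure(list(q_grid = q_grid,
                 buffer_d2o_fraction = buffer_d2o_fraction,
                 protein_deuteration_fraction = protein_deuteration_fraction,
                 hydration_contrast_percent = hydration_contrast_percent,
                 shell_enabled = shell_enabled,
                 probe_radius_ratio = probe_radius_ratio,
                 mode = mode,
                 normalize_I0 = normalize_I0,
                 strict_elements = strict_elements),
            class = "forward_options")
}

# hydrogens whose nearest heavy atom within bond distance is N/O/S exchange
# with the buffer
exchangeable_h <- function(atoms) {
  is_h <- atoms$element == "H"
  out <- logical(nrow(atoms))
  if (!any(is_h)) return(out)
  heavy <- which(atoms$element %in% c("N", "O", "S"))
  if (length(heavy) == 0L) return(out)
  hx <- as.matrix(atoms[is_h, c("x", "y", "z")])
  hv <- as.matrix(atoms[heavy, c("x", "y", "z")])
  d2 <- outer(rowSums(hx^2), rowSums(hv^2), "+") - 2 * hx %*% t(hv)
  out[is_h] <- apply(d2, 1, min) < 1.25^2
  out
}

#' Per-site effective neutron scattering lengths
#'
#' Computes `b_eff = b_coh - rho_solvent * V_displaced` per site (fm), where
#' the solvent scattering-length density is linear in the buffer D2O fraction.
#' Exchangeable hydrogens (bound to N, O or S) take the H/D average at the
#' buffer D2O fraction; non-exchangeable hydrogens take it at the protein
#' deuteration fraction. In residue-bead mode per-residue sums are placed at
#' the Calpha (or the residue centroid if absent).
#'
#' @param model a [structure_model()].
#' @param opts a [forward_options()].
#' @return tibble with columns `x`, `y`, `z`, `b` (fm), one row per site.
#' @export
effective_scattering_lengths <- function(model, opts = forward_options()) {
  atoms <- model$atoms
  ele <- atoms$element
  unknown <- !(ele %in% names(neutron_b_coh))
  if (any(unknown)) {
    if (opts$strict_elements)
      stop("unknown element(s): ", paste(unique(ele[unknown]), collapse = ", "),
           call. = FALSE)
    warning("unknown element(s) ", paste(unique(ele[unknown]), collapse = ", "),
            " treated as carbon", call. = FALSE)
    ele[unknown] <- "C"
  }
  b <- neutron_b_coh[ele]
  V <- displaced_volume[ele] * opts$probe_radius_ratio^3
  is_h <- ele == "H"
  if (any(is_h)) {
    exch <- exchangeable_h(atoms) & is_h
    xb <- opts$buffer_d2o_fraction
    xd <- opts$protein_deuteration_fraction
    b[exch] <- neutron_b_coh["H"] * (1 - xb) + neutron_b_coh["D"] * xb
    b[is_h & !exch] <- neutron_b_coh["H"] * (1 - xd) + neutron_b_coh["D"] * xd
  }
  rho <- solvent_sld(opts$buffer_d2o_fraction)
  sites <- tibble::tibble(x = atoms$x, y = atoms$y, z = atoms$z,
                          b = unname(b - rho * V))
  if (opts$mode == "residue-bead") {
    key <- paste(atoms$chain, atoms$res_id, sep = "|")
    sites <- dplyr::group_by(dplyr::mutate(sites,
                                           .key = key,
                                           .is_ca = atoms$atom_name == "CA"),
                             .data$.key)
    sites <- dplyr::summarise(sites,
      x = if (any(.data$.is_ca)) .data$x[.data$.is_ca][1] else mean(.data$x),
      y = if (any(.data$.is_ca)) .data$y[.data$.is_ca][1] else mean(.data$y),
      z = if (any(.data$.is_ca)) .data$z[.data$.is_ca][1] else mean(.data$z),
      b = sum(.data$b), .groups = "drop")
    sites <- sites[, c("x", "y", "z", "b")]
  }
  sites
}

# dummy beads on a grid layer just outside the van der Waals surface
hydration_shell_sites <- function(atoms, opts, probe = 3, spacing = 3) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- vdw_radii[atoms$element]
  r[is.na(r)] <- 1.7
  pad <- max(r) + probe + spacing
  gx <- seq(min(xyz[, 1]) - pad, max(xyz[, 1]) + pad, by = spacing)
  gy <- seq(min(xyz[, 2]) - pad, max(xyz[, 2]) + pad, by = spacing)
  gz <- seq(min(xyz[, 3]) - pad, max(xyz[, 3]) + pad, by = spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  keep <- logical(nrow(grid))
  block <- max(1L, floor(2e6 / nrow(xyz)))
  at2 <- rowSums(xyz^2)
  for (i0 in seq(1L, nrow(grid), by = block)) {
    idx <- i0:min(i0 + block - 1L, nrow(grid))
    g <- grid[idx, , drop = FALSE]
    d2 <- outer(rowSums(g^2), at2, "+") - 2 * g %*% t(xyz)
    d2[d2 < 0] <- 0
    dsurf <- sqrt(d2) - rep(r, each = length(idx))
    dmin <- apply(matrix(dsurf, nrow = length(idx)), 1, min)
    keep[idx] <- dmin > 0 & dmin <= probe
  }
  shell <- grid[keep, , drop = FALSE]
  b_shell <- (opts$hydration_contrast_percent / 100) *
    solvent_sld(opts$buffer_d2o_fraction) * spacing^3
  tibble::tibble(x = shell[, 1], y = shell[, 2], z = shell[, 3],
                 b = rep(b_shell, nrow(shell)))
}

forward_sites <- function(model, opts) {
  sites <- effective_scattering_lengths(model, opts)
  if (opts$shell_enabled && opts$hydration_contrast_percent != 0)
    sites <- dplyr::bind_rows(sites, hydration_shell_sites(model$atoms, opts))
  sites
}

sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# orientationally averaged Debye double sum over pair distances; exact for
# n_pairs below the binning threshold, distance-binned (0.05 A) above it
debye_sum <- function(xyz, b, q, bin_threshold = 2000L, bin_width = 0.05) {
  n <- nrow(xyz)
  self_term <- sum(b^2)
  if (n == 1L) return(rep(self_term, length(q)))
  d <- as.vector(stats::dist(xyz))
  w <- tcrossprod(b)[lower.tri(matrix(0, n, n))]
  if (n > bin_threshold) {
    bin <- floor(d / bin_width)
    wsum <- as.vector(rowsum(w, bin))
    # weight-averaged distance per bin keeps the binned sum second-order
    # accurate; near-cancelling bins fall back to the bin center
    wr <- as.vector(rowsum(w * d, bin))
    centers <- (as.numeric(rownames(rowsum(w, bin))) + 0.5) * bin_width
    ok <- abs(wsum) > 1e-9 * max(abs(w))
    d <- ifelse(ok, wr / wsum, centers)
    w <- wsum
  }
  I <- numeric(length(q))
  block <- max(1L, floor(4e6 / length(d)))
  for (i0 in seq(1L, length(q), by = block)) {
    idx <- i0:min(i0 + block - 1L, length(q))
    S <- matrix(sinc(outer(q[idx], d)), nrow = length(idx))
    I[idx] <- self_term + 2 * as.vector(S %*% w)
  }
  I
}

#' Theoretical scattering curve via the Debye sum
#'
#' Computes the orientationally averaged intensity
#' `I(q) = sum_j sum_k b_j b_k sin(q r_jk) / (q r_jk)` over all site pairs,
#' with `sinc(0) = 1`, using per-site effective scattering lengths from
#' [effective_scattering_lengths()] plus (optionally) a hydration-shell bead
#' layer. With `normalize_I0` the curve is divided by `I(0) = (sum_j b_j)^2`.
#'
#' @param model a [structure_model()].
#' @param opts a [forward_options()].
#' @return a [sans_curve()] on `opts$q_grid`, labelled by the model id.
#' @export
debye_intensity <- function(model, opts = forward_options()) {
  sites <- forward_sites(model, opts)
  if (all(abs(sites$b) < 1e-9))
    stop("all-zero contrast: degenerate curve", call. = FALSE)
  I <- debye_sum(as.matrix(sites[, c("x", "y", "z")]), sites$b, opts$q_grid)
  if (opts$normalize_I0) {
    I0 <- sum(sites$b)^2
    if (I0 <= .Machine$double.eps * sum(sites$b^2))
      stop("I(0) is zero (contrast-matched): cannot normalize", call. = FALSE)
    I <- I / I0
  }
  sans_curve(opts$q_grid, I, label = model$model_id)
}

#' Contrast-weighted radius of gyration
#'
#' `Rg = sqrt(sum_j b_j |r_j - rbar|^2 / sum_j b_j)` with the b-weighted
#' centroid `rbar`; falls back to unit weights when the total scattering
#' length is non-positive. The hydration shell is not included.
#'
#' @param model a [structure_model()].
#' @param opts a [forward_options()].
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(model, opts = forward_options()) {
  sites <- effective_scattering_lengths(model, opts)
  b <- sites$b
  if (sum(b) <= 0) b <- rep(1, length(b))
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  ctr <- colSums(xyz * b) / sum(b)
  sq <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(b * sq) / sum(b))
}

#' Contrast-weighted pair-distance distribution P(r)
#'
#' Histogram of pairwise site distances weighted by `2 b_j b_k` (distinct
#' pairs, self terms excluded), expressed as a density: the sum of
#' `P * bin_width` equals the total pair weight, so that
#' `I(q) = sum_j b_j^2 + sum_bins P(r) sinc(q r) bin_width` reproduces the
#' Debye sum up to binning error.
#'
#' @param model a [structure_model()].
#' @param opts a [forward_options()]; the shell is not included.
#' @param bin_width histogram bin width in Angstrom.
#' @param normalize_area rescale so the area under P(r) is 1.
#' @return tibble of class `pair_distribution` with columns `r` (bin centers)
#'   and `P`, plus a `bin_width` attribute.
#' @export
pair_distance_distribution <- function(model, opts = forward_options(),
                                       bin_width = 1, normalize_area = FALSE) {
  stopifnot(bin_width > 0)
  sites <- effective_scattering_lengths(model, opts)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 sites for P(r)", call. = FALSE)
  d <- as.vector(stats::dist(xyz))
  w <- 2 * tcrossprod(sites$b)[lower.tri(matrix(0, n, n))]
  n_bins <- floor(max(d) / bin_width) + 1L
  bin <- pmin(floor(d / bin_width), n_bins - 1L)
  P <- numeric(n_bins)
  agg <- rowsum(w, bin)
  P[as.integer(rownames(agg)) + 1L] <- agg / bin_width
  if (normalize_area) P <- P / (sum(P) * bin_width)
  out <- tibble::tibble(r = (seq_len(n_bins) - 0.5) * bin_width, P = P)
  attr(out, "bin_width") <- bin_width
  attr(out, "self_term") <- sum(sites$b^2)
  class(out) <- c("pair_distribution", class(out))
  out
}

#' Theoretical curves for every model in an ensemble
#'
#' @param ensemble a [structure_ensemble()].
#' @param opts a [forward_options()].
#' @param progress print a progress note every 50 models.
#' @return named list of [sans_curve()] objects, one per model, in ensemble
#'   order.
#' @export
batch_curves <- function(ensemble, opts = forward_options(), progress = FALSE) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  curves <- vector("list", length(ensemble$models))
  for (i in seq_along(ensemble$models)) {
    m <- ensemble$models[[i]]
    curves[[i]] <- tryCatch(debye_intensity(m, opts),
      error = function(e) stop("model ", m$model_id, ": ",
                               conditionMessage(e), call. = FALSE))
    if (progress && i %% 50L == 0L)
      message("computed ", i, "/", length(ensemble$models), " curves")
  }
  names(curves) <- vapply(ensemble$models, `[[`, "", "model_id")
  curves
}

# stack curves sharing a q grid into an n_curves x Nq matrix
curve_matrix <- function(curves) {
  q0 <- curves[[1]]$q
  for (cv in curves)
    if (length(cv$q) != length(q0) || any(cv$q != q0))
      stop("curves are not on a common q grid", call. = FALSE)
  m <- do.call(rbind, lapply(curves, function(cv) cv$I))
  rownames(m) <- names(curves)
  m
}
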