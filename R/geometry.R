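#' Parse an atom selection expression
#'
#' Selections use `"chain:residues:atom"` with `*` wildcards, e.g.
#' `"A:220-260:CA"` (Calpha of residues 220-260 in chain A), `"*:*:CA"` (all
#' Calpha). Chains and atom names may be comma-separated lists; residues may
#' be comma-separated single ids or `a-b` ranges.
#'
#' @param expr selection string.
#' @return a predicate function mapping an atom tibble to a logical vector.
#' @export
parse_selection <- function(expr) {
  parts <- strsplit(expr, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("selection must be 'chain:residues:atom', got '", expr, "'", call. = FALSE)
  chains <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  atom_names <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
  res_tokens <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  res_ids <- if (identical(parts[2], "*")) NULL else {
    unlist(lapply(res_tokens, function(tk) {
      if (grepl("-", tk)) {
        ab <- as.integer(strsplit(tk, "-", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else as.integer(tk)
    }))
  }
  function(atoms) {
    keep <- rep(TRUE, nrow(atoms))
    if (!identical(parts[1], "*")) keep <- keep & atoms$chain %in% chains
    if (!is.null(res_ids)) keep <- keep & atoms$res_id %in% res_ids
    if (!identical(parts[3], "*")) keep <- keep & atoms$atom_name %in% atom_names
    keep
  }
}

select_atoms <- function(model, selection) {
  model$atoms[parse_selection(selection)(model$atoms), , drop = FALSE]
}

# optimal proper rotation (Kabsch, via SVD) aligning row-vector set P onto Q
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# superpose P onto Q (rows are points); returns transformed P
superpose_coords <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  R <- kabsch_rotation(Pc, Qc)
  sweep(Pc %*% R, 2, cq, "+")
}

point_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

paired_coords <- function(model_a, model_b, selection) {
  aa <- select_atoms(model_a, selection)
  ab <- select_atoms(model_b, selection)
  ka <- atom_key(aa); kb <- atom_key(ab)
  shared <- intersect(ka, kb)
  missing <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(shared) < 3L)
    stop("selection '", selection, "' pairs only ", length(shared),
         " atoms (need >= 3)",
         if (length(missing)) paste0("; unpaired: ",
           paste(utils::head(missing, 5), collapse = ", ")) else "",
         call. = FALSE)
  list(A = as.matrix(aa[match(shared, ka), c("x", "y", "z")]),
       B = as.matrix(ab[match(shared, kb), c("x", "y", "z")]))
}

#' RMSD after least-squares superposition
#'
#' Pairs atoms by `(chain, residue, atom name)` within the selection, finds
#' the optimal rigid-body superposition (proper rotation only) and reports
#' the RMSD over the paired atoms.
#'
#' @param model_a,model_b [structure_model()] objects.
#' @param selection atom selection (default all Calpha).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(model_a, model_b, selection = "*:*:CA") {
  p <- paired_coords(model_a, model_b, selection)
  point_rmsd(superpose_coords(p$A, p$B), p$B)
}

# selection falling back to all atoms when no Calpha exist (bead models)
default_fit_selection <- function(model) {
  if (any(model$atoms$atom_name == "CA")) "*:*:CA" else "*:*:*"
}

# superpose every model's selected coordinates onto the ensemble mean:
# fit all onto the first, average, then re-fit each onto the average
superposed_ensemble_coords <- function(ensemble, selection = NULL) {
  if (length(ensemble$models) < 2L)
    stop("need at least 2 models", call. = FALSE)
  if (is.null(selection)) selection <- default_fit_selection(ensemble$models[[1]])
  coords <- lapply(ensemble$models, function(m) {
    a <- select_atoms(m, selection)
    if (nrow(a) < 3L) stop("selection '", selection, "' resolves to fewer than 3 atoms",
                           call. = FALSE)
    as.matrix(a[, c("x", "y", "z")])
  })
  n_atoms <- unique(vapply(coords, nrow, 0L))
  if (length(n_atoms) != 1L)
    stop("models differ in selected atom counts; reduce to common atoms first",
         call. = FALSE)
  onto_first <- lapply(coords, superpose_coords, Q = coords[[1]])
  mean_xyz <- Reduce(`+`, onto_first) / length(onto_first)
  list(coords = lapply(coords, superpose_coords, Q = mean_xyz),
       mean = mean_xyz,
       atoms = select_atoms(ensemble$models[[1]], selection))
}

#' Per-model RMSD to the ensemble average structure
#'
#' Superposes all models onto the first, computes the coordinate-mean
#' structure, re-superposes each model onto that mean and reports the RMSD
#' to the mean over the selection (Calpha by default).
#'
#' @param ensemble a [structure_ensemble()] (common atoms across models).
#' @param selection atom selection; default Calpha, falling back to all atoms
#'   for bead models.
#' @return tibble with columns `model_id`, `rmsd` (Angstrom), in ensemble
#'   order.
#' @export
rmsd_to_average <- function(ensemble, selection = NULL) {
  sup <- superposed_ensemble_coords(ensemble, selection)
  tibble::tibble(
    model_id = vapply(ensemble$models, `[[`, "", "model_id"),
    rmsd = vapply(sup$coords, point_rmsd, 0, B = sup$mean))
}

#' Root-mean-square fluctuation per residue
#'
#' After superposing every model onto the ensemble mean (the
#' [rmsd_to_average()] protocol), computes per-selected-atom
#' `RMSF = sqrt(mean_models |r - rbar|^2)` about the post-fit mean position.
#'
#' @param ensemble a [structure_ensemble()].
#' @param selection atom selection (default Calpha).
#' @param by_chain also return the per-residue average over chains (subunit
#'   average for symmetric oligomers).
#' @return tibble with columns `chain`, `res_id`, `rmsf` (Angstrom); with
#'   `by_chain = FALSE` collapsed over chains to `res_id`, `rmsf`.
#' @export
rmsf <- function(ensemble, selection = NULL, by_chain = TRUE) {
  sup <- superposed_ensemble_coords(ensemble, selection)
  mean_xyz <- Reduce(`+`, sup$coords) / length(sup$coords)
  msd <- Reduce(`+`, lapply(sup$coords, function(X) rowSums((X - mean_xyz)^2))) /
    length(sup$coords)
  out <- tibble::tibble(chain = sup$atoms$chain, res_id = sup$atoms$res_id,
                        rmsf = sqrt(msd))
  if (!by_chain)
    out <- dplyr::summarise(dplyr::group_by(out, .data$res_id),
                            rmsf = mean(.data$rmsf), .groups = "drop")
  out
}

# first principal axis of the selected coordinates (largest-variance
# direction; the long axis of an elongated channel)
principal_axis <- function(xyz) {
  e <- eigen(stats::cov(xyz), symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Probe-sphere pore-radius profile
#'
#' A simplified pore profile: at each point along the axis the pore radius is
#' the smallest `(distance to an atom center) - (atom van der Waals radius)`,
#' clamped to `[0, cap]`. This is an approximation to pathway-following tools
#' (HOLE, CHAP) suitable for near-axial channels.
#'
#' @param model a [structure_model()].
#' @param axis either `NULL` (use the first principal axis of the Calpha
#'   coordinates through their centroid) or a 2x3 matrix of two points
#'   defining the axis.
#' @param z_range range of axis coordinates (Angstrom, relative to the axis
#'   anchor); default spans the atom projections.
#' @param step spacing of profile points (Angstrom).
#' @param radii named van der Waals radii per element; unknown elements get
#'   1.7 Angstrom.
#' @param cap maximum reported radius (Angstrom).
#' @return tibble of class `pore_profile` with columns `axis_coordinate`,
#'   `radius`, plus attributes `min_radius`, `axis_point`, `axis_direction`.
#' @export
pore_profile <- function(model, axis = NULL, z_range = NULL, step = 0.5,
                         radii = vdw_radii, cap = 10) {
  atoms <- model$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(axis)) {
    ca <- xyz[atoms$atom_name == "CA", , drop = FALSE]
    if (nrow(ca) < 3L) ca <- xyz
    p0 <- colMeans(ca)
    u <- principal_axis(ca)
  } else {
    axis <- as.matrix(axis)
    stopifnot(nrow(axis) == 2L, ncol(axis) == 3L)
    p0 <- axis[1, ]
    u <- axis[2, ] - axis[1, ]
    u <- u / sqrt(sum(u^2))
  }
  t_atom <- as.vector(sweep(xyz, 2, p0) %*% u)
  if (is.null(z_range)) z_range <- range(t_atom)
  z <- seq(z_range[1], z_range[2], by = step)
  r_atom <- radii[atoms$element]
  r_atom[is.na(r_atom)] <- 1.7
  radius <- vapply(z, function(t) {
    p <- p0 + t * u
    d <- sqrt(rowSums(sweep(xyz, 2, p)^2)) - r_atom
    min(max(min(d), 0), cap)
  }, 0)
  if (all(radius >= cap))
    warning("no atoms within the radius cap anywhere along the axis", call. = FALSE)
  out <- tibble::tibble(axis_coordinate = z, radius = radius)
  attr(out, "min_radius") <- min(radius)
  attr(out, "axis_point") <- p0
  attr(out, "axis_direction") <- u
  class(out) <- c("pore_profile", class(out))
  out
}

#' Minimum pore radius
#'
#' @param profile a [pore_profile()].
#' @return the minimum radius (Angstrom).
#' @export
min_pore_radius <- function(profile) attr(profile, "min_radius")

#' Center-of-mass spread metric
#'
#' Mean over groups of the distance between each group's (unweighted) center
#' of mass and a reference center of mass. With one group per subunit this is
#' the subunit-averaged gating descriptor (e.g. the M2 spread: distance from
#' the pore center to the upper pore-lining helices).
#'
#' @param model a [structure_model()].
#' @param ref_selection selection for the reference center.
#' @param group_selections character vector of group selections.
#' @return tibble with one row per group (`selection`, `distance`) plus a
#'   `value` attribute holding the mean distance.
#' @export
com_spread <- function(model, ref_selection, group_selections) {
  com <- function(sel) {
    a <- select_atoms(model, sel)
    if (nrow(a) == 0L) stop("empty selection '", sel, "'", call. = FALSE)
    colMeans(as.matrix(a[, c("x", "y", "z")]))
  }
  ref <- com(ref_selection)
  d <- vapply(group_selections, function(s) sqrt(sum((com(s) - ref)^2)), 0)
  out <- tibble::tibble(selection = group_selections, distance = unname(d))
  attr(out, "value") <- mean(d)
  out
}

#' @export
autoplot.pore_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$axis_coordinate, y = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axis coordinate (Å)", y = "pore radius (Å)")
}
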