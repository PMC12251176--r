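#' Filter an ensemble by per-model confidence
#'
#' Retains models whose `mean_confidence` is greater than or equal to the
#' cutoff (inclusive), preserving order.
#'
#' @param ensemble a [structure_ensemble()].
#' @param cutoff confidence cutoff in `[0, 100]`.
#' @return a filtered [structure_ensemble()].
#' @export
filter_by_confidence <- function(ensemble, cutoff) {
  if (cutoff < 0 || cutoff > 100)
    stop("cutoff must be in [0, 100], got ", cutoff, call. = FALSE)
  keep <- vapply(ensemble$models, `[[`, 0, "mean_confidence") >= cutoff
  if (!any(keep))
    stop("no models with mean confidence >= ", cutoff, call. = FALSE)
  structure_ensemble(ensemble$models[keep], ensemble$provenance)
}

#' Principal component analysis of scattering curves
#'
#' Mean-centers the curves (no per-q rescaling) and projects onto the
#' smallest number of components whose cumulative explained variance exceeds
#' 95%, with a floor of 2 components. A deterministic sign convention is
#' applied: each component is flipped so its largest-magnitude loading is
#' positive.
#'
#' @param curves list of [sans_curve()] objects on a common q grid (>= 3).
#' @param variance_target cumulative explained-variance ratio to exceed.
#' @return object of class `sans_pca`: `n_components`,
#'   `explained_variance_ratio`, `projections` (tibble, `model_id` +
#'   `PC1..PCn`), `loadings` (components in rows, on the q grid),
#'   `mean_curve`, `q`.
#' @export
pca_curves <- function(curves, variance_target = 0.95) {
  if (length(curves) < 3L) stop("need at least 3 curves for PCA", call. = FALSE)
  X <- curve_matrix(curves)
  tot_var <- sum(apply(X, 2, stats::var))
  if (!is.finite(tot_var) || tot_var <= .Machine$double.eps * mean(X^2))
    stop("degenerate PCA: curves are identical (zero variance)", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  n_comp <- max(2L, which(cumsum(evr) > variance_target)[1])
  n_comp <- min(n_comp, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(n_comp)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  proj <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(proj) <- paste0("PC", seq_len(n_comp))
  ids <- names(curves)
  if (is.null(ids)) ids <- vapply(curves, curve_label, "")
  proj <- dplyr::bind_cols(tibble::tibble(model_id = ids), proj)
  q <- curves[[1]]$q
  structure(list(n_components = n_comp,
                 explained_variance_ratio = evr,
                 projections = proj,
                 loadings = t(rot),
                 mean_curve = sans_curve(q, colMeans(X), label = "mean"),
                 q = q),
            class = "sans_pca")
}

#' @export
print.sans_pca <- function(x, ...) {
  cat(sprintf("<sans_pca> %d curves, %d components (%.1f%% variance)\n",
              nrow(x$projections), x$n_components,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
  invisible(x)
}

pca_coords <- function(embedding) {
  as.matrix(embedding$projections[, paste0("PC", seq_len(embedding$n_components))])
}

#' Agglomerative clustering of a curve embedding
#'
#' Ward-linkage hierarchical clustering on Euclidean distances in principal
#' component space. Labels are `0..k-1`, assigned in order of increasing
#' cluster mean along PC1 (label 0 = lower PC1).
#'
#' @param embedding a [pca_curves()] result (or a numeric coordinate matrix
#'   whose first column plays the role of PC1).
#' @param k number of clusters (default 2).
#' @return integer vector of labels in `0..k-1`.
#' @export
cluster_embedding <- function(embedding, k = 2L) {
  X <- if (inherits(embedding, "sans_pca")) pca_coords(embedding) else as.matrix(embedding)
  if (nrow(X) < k) stop("fewer points (", nrow(X), ") than clusters (", k, ")",
                        call. = FALSE)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  pc1_means <- tapply(X[, 1], raw, mean)
  remap <- rank(pc1_means, ties.method = "first") - 1L
  unname(remap[as.character(raw)])
}

#' Mean silhouette score
#'
#' Standard silhouette: for each point, `s = (b - a) / max(a, b)` with `a`
#' the mean distance to its own cluster (excluding itself) and `b` the
#' smallest mean distance to another cluster; singleton clusters contribute 0.
#'
#' @param embedding a [pca_curves()] result or coordinate matrix.
#' @param labels cluster labels (any values; >= 2 distinct).
#' @return mean silhouette over points, in `[-1, 1]`.
#' @export
mean_silhouette <- function(embedding, labels) {
  X <- if (inherits(embedding, "sans_pca")) pca_coords(embedding) else as.matrix(embedding)
  n <- nrow(X)
  if (length(labels) != n) stop("labels length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least 2 clusters", call. = FALSE)
  if (n < 3L) stop("silhouette needs at least 3 points", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(unique(labels[!own]),
                    function(l) mean(D[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Confidence-threshold sweep for cluster quality
#'
#' For each confidence threshold: retain models at or above it, run
#' [pca_curves()] on their theoretical curves, cluster into `k` groups and
#' score the clustering by mean silhouette. The chosen threshold is the
#' smallest one attaining the maximum silhouette (ties form a reported
#' plateau). Thresholds retaining fewer than 3 models, or yielding a
#' degenerate PCA, are recorded with `NA` silhouette and skipped for the
#' argmax. Per cluster, the representative is the retained model with the
#' highest mean confidence (ties broken by ensemble order).
#'
#' @param ensemble a [structure_ensemble()].
#' @param curves theoretical curves parallel to `ensemble$models` (e.g. from
#'   [batch_curves()]).
#' @param thresholds numeric vector of cutoffs, or `"auto"`: the base cutoff
#'   plus every distinct per-model confidence in `[base_cutoff, max)`.
#' @param base_cutoff lowest cutoff considered in auto mode (default 75).
#' @param k number of clusters (default 2).
#' @return object of class `cluster_sweep`: `sweep` tibble
#'   (`threshold`, `n_retained`, `silhouette`), `best_threshold`,
#'   `best_silhouette`, `plateau`, `labels` tibble (`model_id`,
#'   `mean_confidence`, `label`, PC coordinates), `representatives` tibble,
#'   `pca` (embedding at the best threshold), `k`.
#' @export
threshold_sweep <- function(ensemble, curves, thresholds = "auto",
                            base_cutoff = 75, k = 2L) {
  stopifnot(length(curves) == length(ensemble$models))
  scores <- vapply(ensemble$models, `[[`, 0, "mean_confidence")
  if (identical(thresholds, "auto")) {
    hi <- max(scores)
    thresholds <- sort(unique(c(base_cutoff, scores[scores >= base_cutoff & scores < hi])))
  } else {
    thresholds <- sort(unique(as.numeric(thresholds)))
  }
  if (length(thresholds) == 0L) stop("no thresholds to sweep", call. = FALSE)

  eval_threshold <- function(t) {
    keep <- which(scores >= t)
    if (length(keep) < 3L) return(list(sil = NA_real_, n = length(keep)))
    emb <- tryCatch(pca_curves(curves[keep]), error = function(e) NULL)
    if (is.null(emb)) return(list(sil = NA_real_, n = length(keep)))
    labels <- cluster_embedding(emb, k = k)
    list(sil = mean_silhouette(emb, labels), n = length(keep),
         keep = keep, emb = emb, labels = labels)
  }
  evals <- lapply(thresholds, eval_threshold)
  sweep_tbl <- tibble::tibble(
    threshold = thresholds,
    n_retained = vapply(evals, `[[`, 0L, "n"),
    silhouette = vapply(evals, `[[`, 0, "sil"))
  if (all(is.na(sweep_tbl$silhouette)))
    stop("no threshold yields a valid clustering", call. = FALSE)
  best_sil <- max(sweep_tbl$silhouette, na.rm = TRUE)
  plateau <- thresholds[!is.na(sweep_tbl$silhouette) &
                          sweep_tbl$silhouette == best_sil]
  best_i <- which(!is.na(sweep_tbl$silhouette) &
                    sweep_tbl$silhouette == best_sil)[1]
  best <- evals[[best_i]]

  ids <- vapply(ensemble$models, `[[`, "", "model_id")
  labels_tbl <- dplyr::bind_cols(
    tibble::tibble(model_id = ids[best$keep],
                   mean_confidence = scores[best$keep],
                   label = best$labels),
    best$emb$projections[, -1, drop = FALSE])
  reps <- dplyr::slice(
    dplyr::group_by(labels_tbl, .data$label),
    which.max(.data$mean_confidence))
  reps <- dplyr::ungroup(reps)[, c("label", "model_id", "mean_confidence")]

  structure(list(sweep = sweep_tbl,
                 best_threshold = thresholds[best_i],
                 best_silhouette = best_sil,
                 plateau = plateau,
                 labels = labels_tbl,
                 representatives = reps,
                 pca = best$emb,
                 k = k),
            class = "cluster_sweep")
}

#' @export
print.cluster_sweep <- function(x, ...) {
  cat(sprintf(paste0("<cluster_sweep> %d thresholds; best %.4g ",
                     "(silhouette %.3f, %d models, %d clusters)\n"),
              nrow(x$sweep), x$best_threshold, x$best_silhouette,
              x$sweep$n_retained[x$sweep$threshold == x$best_threshold][1], x$k))
  cat("representatives:",
      paste(sprintf("[%d] %s", x$representatives$label, x$representatives$model_id),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cluster_sweep <- function(x, ...) x$sweep

#' @importFrom generics glance
#' @export
glance.cluster_sweep <- function(x, ...) {
  tibble::tibble(best_threshold = x$best_threshold,
                 best_silhouette = x$best_silhouette,
                 n_retained = nrow(x$labels),
                 n_clusters = x$k,
                 plateau_lo = min(x$plateau),
                 plateau_hi = max(x$plateau))
}

#' @export
autoplot.cluster_sweep <- function(object, ...) {
  ggplot2::ggplot(object$sweep,
                  ggplot2::aes(x = .data$threshold, y = .data$silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_threshold, linetype = 2) +
    ggplot2::labs(x = "confidence cutoff", y = "mean silhouette")
}

#' Scatter plot of the curve embedding coloured by cluster
#'
#' @param sweep a [threshold_sweep()] result.
#' @return a ggplot object.
#' @export
plot_embedding <- function(sweep) {
  ggplot2::ggplot(sweep$labels,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = factor(.data$label))) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "cluster")
}
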