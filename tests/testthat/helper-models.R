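# shared fixture builders: plain bead models and analytic-friendly options

bead_atoms <- function(xyz, element = "C", confidence = 90) {
  xyz <- matrix(xyz, ncol = 3)
  tibble::tibble(element = element, atom_name = "CA", res_name = "ALA",
                 res_id = seq_len(nrow(xyz)), chain = "A",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 confidence = confidence)
}

bead_model <- function(xyz, id = "toy", element = "C", confidence = 90) {
  structure_model(id, bead_atoms(xyz, element, confidence))
}

random_bead_model <- function(n, scale = 8, id = "rand", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bead_model(matrix(stats::runif(3 * n, -scale, scale), ncol = 3), id = id)
}

# analytic settings: no hydration shell, raw (unnormalized) intensities
bare_opts <- function(q_grid = seq(0, 0.45, length.out = 201), ...) {
  forward_options(q_grid = q_grid, shell_enabled = FALSE,
                  normalize_I0 = FALSE, ...)
}

# normalized curves as the clustering stages consume them
norm_opts <- function(q_grid = seq(0, 0.45, length.out = 201), ...) {
  forward_options(q_grid = q_grid, shell_enabled = FALSE, ...)
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_r <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_move <- function(model, R = random_rotation(), shift = c(3, -7, 11)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2, shift, "+")
  a <- model$atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  structure_model(model$model_id, a)
}

# independent brute-force silhouette used as an oracle
silhouette_brute <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(X, 2, X[i, ])^2))
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (length(same) == 0L) { s[i] <- 0; next }
    a <- mean(di[same])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(di[labels == l]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
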