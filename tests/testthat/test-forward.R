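test_that("Debye sum reproduces the two-site closed form", {
  set.seed(11)
  for (rep in 1:20) {
    d <- runif(1, 2, 40)
    ele <- sample(c("H", "C", "N", "O", "S"), 1)
    x_d2o <- runif(1)
    opts <- bare_opts(buffer_d2o_fraction = x_d2o)
    m <- bead_model(rbind(c(0, 0, 0), c(d, 0, 0)), element = ele)
    b <- effective_scattering_lengths(m, opts)$b[1]
    cv <- debye_intensity(m, opts)
    q <- opts$q_grid
    closed <- 2 * b^2 * (1 + ifelse(q == 0, 1, sin(q * d) / (q * d)))
    expect_lt(max(abs(cv$I - closed) / abs(closed)), 1e-10)
  }
})

test_that("single point scatterer gives a flat curve and sinc(0)=1 at q=0", {
  m <- bead_model(c(1, 2, 3))
  cv <- debye_intensity(m, bare_opts())
  expect_true(all(cv$I == cv$I[1]))
  cvn <- debye_intensity(m, norm_opts())
  expect_equal(cvn$I[1], 1)
})

test_that("intensity is invariant under rigid motion and site order", {
  m <- random_bead_model(40, seed = 5)
  opts <- bare_opts()
  I0 <- debye_intensity(m, opts)$I
  I_mov <- debye_intensity(rigid_move(m, random_rotation(6)), opts)$I
  expect_lt(max(abs(I_mov - I0) / abs(I0)), 1e-10)
  perm <- structure_model("p", m$atoms[sample(nrow(m$atoms)), ])
  expect_lt(max(abs(debye_intensity(perm, opts)$I - I0) / abs(I0)), 1e-10)
})

test_that("effective scattering lengths honour contrast and exchange", {
  opts <- bare_opts(buffer_d2o_fraction = 1)
  # exchangeable H bound to N takes the deuterium length at full exchange
  atoms <- tibble::tibble(element = c("N", "H"), atom_name = c("N", "H"),
                          res_name = "ALA", res_id = 1L, chain = "A",
                          x = c(0, 1.0), y = 0, z = 0, confidence = 90)
  b <- effective_scattering_lengths(structure_model("m", atoms), opts)$b
  expect_equal(b[2], 6.671 - 0.636 * 5.15, tolerance = 1e-12)
  # far from any N/O/S the hydrogen is non-exchangeable
  atoms$x[2] <- 5
  b2 <- effective_scattering_lengths(structure_model("m", atoms), opts)$b
  expect_equal(b2[2], -3.7406 - 0.636 * 5.15, tolerance = 1e-12)
  # unknown element falls back to carbon with a warning, or errors in strict mode
  atoms$element[2] <- "XX"
  expect_warning(
    b3 <- effective_scattering_lengths(structure_model("m", atoms), opts)$b,
    "carbon")
  expect_equal(b3[2], 6.6511 - 0.636 * 16.44, tolerance = 1e-12)
  expect_error(effective_scattering_lengths(
    structure_model("m", atoms), bare_opts(strict_elements = TRUE)),
    "unknown element")
})

test_that("identical residues get identical bead values in residue-bead mode", {
  m <- bead_model(rbind(c(0, 0, 0), c(20, 0, 0)))
  sites <- effective_scattering_lengths(m, bare_opts(mode = "residue-bead"))
  expect_equal(sites$b[1], sites$b[2])
  # bead and atomic modes agree at q = 0 after identical normalization
  q <- seq(0, 0.45, length.out = 11)
  Ia <- debye_intensity(m, norm_opts(q_grid = q, mode = "atomic"))$I
  Ib <- debye_intensity(m, norm_opts(q_grid = q, mode = "residue-bead"))$I
  expect_equal(Ia[1], Ib[1])
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(bead_model(rbind(c(-5, 0, 0), c(5, 0, 0)))), 5)
  expect_equal(radius_of_gyration(bead_model(c(4, 4, 4))), 0)
  # N sites uniformly on a circle of radius R: Rg = R
  R <- 7.3; N <- 24
  ang <- 2 * pi * (0:(N - 1)) / N
  ring <- bead_model(cbind(R * cos(ang), R * sin(ang), 0))
  expect_equal(radius_of_gyration(ring), R, tolerance = 1e-12)
})

test_that("Guinier slope agrees with the direct radius of gyration", {
  opts <- bare_opts(q_grid = seq(0, 0.2, length.out = 201))
  for (seed in 1:5) {
    m <- random_bead_model(100, scale = 8, seed = seed)
    rg <- radius_of_gyration(m, opts)
    cv <- debye_intensity(m, opts)
    keep <- cv$q > 0 & cv$q * rg < 0.5
    fit <- stats::lm(log(I) ~ I(q^2), data = cv[keep, ])
    rg_fit <- sqrt(-3 * coef(fit)[[2]])
    expect_lt(abs(rg_fit - rg) / rg, 0.02)
  }
})

test_that("P(r) transforms back to the Debye intensity", {
  opts <- bare_opts()
  m <- random_bead_model(50, scale = 5, seed = 21)
  pr <- pair_distance_distribution(m, opts, bin_width = 0.1)
  bw <- attr(pr, "bin_width")
  sites <- effective_scattering_lengths(m, opts)
  # total pair weight: sum over distinct pairs of 2 b_j b_k
  W <- tcrossprod(sites$b)
  expect_equal(sum(pr$P) * bw, sum(W[lower.tri(W)]) * 2, tolerance = 1e-10)
  I_direct <- debye_intensity(m, opts)$I
  I_from_pr <- attr(pr, "self_term") +
    vapply(opts$q_grid,
           function(q) sum(pr$P * ifelse(pr$r * q == 0, 1,
                                         sin(q * pr$r) / (q * pr$r)) * bw), 0)
  expect_lt(max(abs(I_from_pr - I_direct) / abs(I_direct)), 1e-3)
  prn <- pair_distance_distribution(m, opts, bin_width = 0.1,
                                    normalize_area = TRUE)
  expect_equal(sum(prn$P) * bw, 1, tolerance = 1e-12)
})

test_that("two-site P(r) puts all mass in one bin", {
  m <- bead_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  pr <- pair_distance_distribution(m, bare_opts(), bin_width = 1,
                                   normalize_area = TRUE)
  expect_equal(sum(pr$P > 0), 1L)
  expect_equal(pr$r[pr$P > 0], 10.5)
})

test_that("distance-binned and exact Debye sums agree", {
  m <- random_bead_model(80, scale = 5, seed = 31)
  opts <- bare_opts()
  sites <- effective_scattering_lengths(m, opts)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  exact <- sanstates:::debye_sum(xyz, sites$b, opts$q_grid)
  binned <- sanstates:::debye_sum(xyz, sites$b, opts$q_grid, bin_threshold = 1L)
  expect_lt(max(abs(binned - exact) / abs(exact)), 1e-4)
})

test_that("batch curves preserve order, normalization, and report errors", {
  m <- random_bead_model(20, seed = 41)
  ens <- structure_ensemble(list(m, structure_model("b", m$atoms),
                                 structure_model("c", m$atoms)))
  curves <- batch_curves(ens, norm_opts())
  expect_named(curves, c("rand", "b", "c"))
  expect_equal(curves[[1]]$I, curves[[3]]$I)
  # two distinct states: normalized curves coincide at q = 0, differ inside
  fx <- make_two_state_ensemble(fixture_spec(n_models_per_state = 1,
                                             n_intermediates = 0, jitter_sd = 0,
                                             seed = 1))
  cs <- batch_curves(fx$ensemble, norm_opts())
  expect_equal(cs[[1]]$I[1], cs[[2]]$I[1])
  expect_gt(max(abs(cs[[1]]$I - cs[[2]]$I)), 1e-3)
  expect_error(structure_ensemble(list()), "empty")
})

test_that("zero-contrast models are rejected as degenerate", {
  m <- bead_model(rbind(c(0, 0, 0), c(5, 0, 0)))
  # solve the D2O fraction at which carbon's b_eff vanishes (contrast match)
  f_match <- uniroot(function(x) 6.6511 - sanstates:::solvent_sld(x) * 16.44,
                     c(0, 1), tol = 1e-14)$root
  expect_error(debye_intensity(m, bare_opts(buffer_d2o_fraction = f_match)),
               "degenerate|zero")
})

test_that("hydration shell adds surface beads that perturb the curve", {
  m <- random_bead_model(30, scale = 6, seed = 51)
  shell_on <- debye_intensity(m, forward_options(shell_enabled = TRUE))
  shell_off <- debye_intensity(m, forward_options(shell_enabled = FALSE))
  expect_false(isTRUE(all.equal(shell_on$I, shell_off$I)))
  expect_equal(shell_on$I[1], 1)  # I(0) normalization includes the shell
})
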