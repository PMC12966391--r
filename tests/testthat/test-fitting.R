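test_that("the tensor fit recovers noise-free tensors to high precision", {
  sch <- four_shell_protocol(1)
  # anisotropic tensor at an oblique orientation
  v <- c(1, 2, 2) / 3
  R <- cbind(v, c(-2, 1, 0) / sqrt(5), c(2, 4, -5) / (3 * sqrt(5)))
  D <- R %*% diag(c(1.6e-3, 0.4e-3, 0.3e-3)) %*% t(R)
  fit <- fit_dti(sch, tensor_signal(sch, D))
  expect_equal(fit$evals[1, ], c(1.6e-3, 0.4e-3, 0.3e-3), tolerance = 1e-6)
  expect_lt(angle_deg(fit$evecs[[1]][, 1], v), 1e-3)
  expect_lt(fit$mse[1], 1e-15)

  # isotropic recovery
  iso <- fit_dti(sch, tensor_signal(sch, diag(rep(3.0e-3, 3))))
  expect_lt(iso$FA[1], 1e-6)
  expect_equal(iso$MD[1], 3.0e-3, tolerance = 1e-6)

  # degenerate designs error with a named deficiency
  b0only <- make_scheme(rep(0, 8), matrix(0, 8, 3))
  expect_error(fit_dti(b0only, rep(1, 8)), "weighted volumes")
  collinear <- make_scheme(c(0, rep(1000, 6)),
                           rbind(c(0, 0, 0), matrix(rep(c(0, 0, 1), 6),
                                                    ncol = 3, byrow = TRUE)))
  expect_error(fit_dti(collinear, rep(0.5, 7)), "rank")
  expect_warning(fit_dti(sch, pmax(tensor_signal(sch, D) - 0.02, 0)),
                 "floored")
})

test_that("the tensor fit is rotation-equivariant", {
  sch <- four_shell_protocol(2)
  th <- 0.8
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  D <- diag(c(1.5e-3, 0.4e-3, 0.4e-3))
  sig <- tensor_signal(sch, D)
  # the same signal vector observed under rotated gradients implies the
  # rotated tensor: epsilon_1 must follow the gradient rotation
  sch_rot <- make_scheme(sch$bvals, sch$bvecs %*% t(R))
  f1 <- fit_dti(sch, sig)
  f2 <- fit_dti(sch_rot, sig)
  expect_equal(f2$evals, f1$evals, tolerance = 1e-9)
  expect_lt(angle_deg(f2$evecs[[1]][, 1], R %*% f1$evecs[[1]][, 1]), 1e-5)
})

test_that("the dispersed-compartment fit round-trips noise-free signals", {
  sch <- four_shell_protocol(1)
  truth <- bnoddi_params(0.1, 0.6, 1.1, 0.4, 0.8,
                         kappa1 = kappa_from_odi(0.2),
                         kappa2 = 0.5 * kappa_from_odi(0.2))
  sig <- bingham_noddi_signal(sch, truth)
  fit <- fit_bingham_noddi(sch, sig, seed = 1)
  co <- coef(fit)[1, ]
  expect_lt(abs(co["f_csf"] - 0.1), 0.02)
  expect_lt(abs(co["nu"] - 0.6), 0.02)
  expect_lt(abs(co["ODI"] - 0.2), 0.02)
  expect_lt(angle_deg(fit$mu[1, ], bingham_frame(1.1, 0.4)[1, ]), 5)
  expect_lt(fit$mse[1], 1e-8)
  expect_false(fit$degenerate[1])
})

test_that("fitter flags pure-CSF degeneracy instead of erroring", {
  sch <- four_shell_protocol(1)
  sig <- bingham_noddi_signal(sch, bnoddi_params(1, 0.5))
  fit <- fit_bingham_noddi(sch, sig, seed = 2)
  expect_gte(coef(fit)[1, "f_csf"], 0.98)
  expect_true(fit$degenerate[1])
})

test_that("fits score the fibre axis antipodally", {
  sch <- four_shell_protocol(3)
  p1 <- bnoddi_params(0.1, 0.7, 0.6, 1.0, 0.3, kappa1 = 12, kappa2 = 3)
  p2 <- bnoddi_params(0.1, 0.7, pi - 0.6, 1.0 + pi, -0.3, kappa1 = 12,
                      kappa2 = 3)  # same distribution, antipodal axis
  s1 <- bingham_noddi_signal(sch, p1)
  s2 <- bingham_noddi_signal(sch, p2)
  expect_equal(s1, s2, tolerance = 1e-12)
  f1 <- fit_bingham_noddi(sch, s1, seed = 4)
  f2 <- fit_bingham_noddi(sch, s2, seed = 4)
  expect_equal(f1$mse, f2$mse, tolerance = 1e-10)
  expect_lt(angle_deg(f1$mu[1, ], f2$mu[1, ]), 1e-3)
})

test_that("a single-shell scheme is rejected; two shells are the floor", {
  single <- make_scheme(c(0, rep(1000, 20)),
                        rbind(c(0, 0, 0), sphere_directions(20, 1)))
  expect_error(fit_bingham_noddi(single, rep(0.5, 21)), "two distinct")
  two <- two_shell_protocol(1)
  sig <- bingham_noddi_signal(two, bnoddi_params(0.1, 0.6, 0.5, 0.5, 0,
                                                 kappa1 = 8, kappa2 = 2))
  fit <- fit_bingham_noddi(two, sig, seed = 1)
  expect_lt(fit$mse[1], 1e-8)
})

test_that("parameter recovery holds over random draws, noise-free and noisy", {
  sch <- four_shell_protocol(0)
  n <- 25
  truths <- lapply(seq_len(n), function(i) random_bnoddi(1000 + i))
  sig <- t(vapply(truths, function(p) bingham_noddi_signal(sch, p),
                  numeric(150)))
  fit <- fit_bingham_noddi(sch, sig, seed = 5)
  err_f <- abs(coef(fit)[, "f_csf"] - vapply(truths, `[[`, 0, "f_csf"))
  err_nu <- abs(coef(fit)[, "nu"] - vapply(truths, `[[`, 0, "nu"))
  expect_lt(median(err_f), 0.01)
  expect_lt(median(err_nu), 0.01)

  noisy <- add_rician_noise(sig, snr = 30, seed = 6)
  fitn <- fit_bingham_noddi(sch, noisy, seed = 7)
  errn_f <- abs(coef(fitn)[, "f_csf"] - vapply(truths, `[[`, 0, "f_csf"))
  errn_nu <- abs(coef(fitn)[, "nu"] - vapply(truths, `[[`, 0, "nu"))
  expect_lt(median(errn_f), 0.05)
  expect_lt(median(errn_nu), 0.05)
  # fit-quality on noisy data sits at the expected order of magnitude
  expect_true(all(fitn$mse > 1e-4 & fitn$mse < 1e-2))
})

test_that("mse_map reproduces residual arithmetic", {
  sch <- four_shell_protocol(1)
  D <- diag(c(1.2e-3, 0.5e-3, 0.5e-3))
  sig <- tensor_signal(sch, D)
  fit <- fit_dti(sch, sig)
  expect_lt(mse_map(fit, signals = matrix(sig, 1)), 1e-15)
  # constant offset delta on normalized attenuations gives MSE = delta^2
  delta <- 0.03
  shifted <- (sig + delta) * fit$s0
  # refit-free: same fit object, shifted observations
  expect_equal(unname(mse_map(fit, signals = matrix(shifted, 1))), delta^2,
               tolerance = 1e-6)
  expect_error(mse_map(fit, signals = matrix(sig[-1], 1)), "volumes")
})
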