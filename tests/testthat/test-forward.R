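test_that("ball, stick, zeppelin and tortuosity obey their closed forms", {
  expect_equal(ball_signal(0, 3.0e-9), 1)
  expect_equal(ball_signal(1000, 3.0e-9), exp(-3))
  b <- seq(0, 3000, by = 500)
  expect_true(all(diff(ball_signal(b, 3.0e-9)) < 0))  # monotone in b

  mu <- c(0, 0, 1)
  expect_equal(stick_signal(c(1, 0, 0), 1000, mu), 1)        # perpendicular
  expect_equal(stick_signal(mu, 1000, mu, 1.7e-9), exp(-1.7))
  g <- c(1, 1, 1) / sqrt(3)
  expect_equal(stick_signal(g, 2000, mu), stick_signal(g, 2000, -mu))

  lp <- 1.7e-9
  expect_equal(zeppelin_signal(g, 1000, mu, lp, lp), ball_signal(1000, lp))
  expect_equal(zeppelin_signal(g, 1000, mu, lp, 0), stick_signal(g, 1000, mu, lp))
  expect_equal(zeppelin_signal(c(1, 0, 0), 1000, mu, lp, 0.5e-9),
               exp(-1000 * 0.5e-3))
  expect_error(zeppelin_signal(g, 1000, mu, lp, 2e-9), "lambda_perp")

  expect_equal(tortuosity_perp(1.7e-9, 1), 0)
  expect_equal(tortuosity_perp(1.7e-9, 0), 1.7e-9)
  expect_equal(tortuosity_perp(1.7e-9, 0.5), 0.85e-9)
  expect_error(tortuosity_perp(1.7e-9, 1.2), "nu")
})

test_that("bingham_odf is a normalized antipodal density matching a Watson oracle", {
  frame <- bingham_frame(0.7, 1.1, 0.4)
  set.seed(1)
  n <- matrix(rnorm(300), 100, 3)
  n <- n / sqrt(rowSums(n^2))

  # uniform limit
  expect_equal(bingham_odf(n, frame, 0, 0), rep(1 / (4 * pi), 100))

  # normalization: integrate the density over the sphere by an independent
  # uniform Monte-Carlo-free lattice (Fibonacci-type) rule
  i <- seq_len(2000)
  z <- (2 * i - 1) / 2000 - 1
  phi <- i * pi * (3 - sqrt(5))
  lat <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  dens <- bingham_odf(lat, frame, 25, 5)
  expect_equal(mean(dens) * 4 * pi, 1, tolerance = 1e-3)

  # Watson oracle at kappa1 == kappa2, 100 directions, 1e-6 relative
  for (k in c(1, 16, 100)) {
    expect_equal(bingham_odf(n, frame, k, k), watson_density(n, frame[1, ], k),
                 tolerance = 1e-6)
  }

  # antipodal symmetry
  expect_equal(bingham_odf(n, frame, 25, 5), bingham_odf(-n, frame, 25, 5))

  expect_error(bingham_odf(n, matrix(1, 3, 3), 2, 1), "orthonormal")
  expect_error(bingham_odf(n, frame, 1, 2), "kappa")
})

test_that("the composite signal has the right limits and invariances", {
  sch <- four_shell_protocol(1)
  b0 <- sch$bvals <= sch$b0_threshold

  p <- bnoddi_params(0.2, 0.6, 0.9, 0.3, 0.7, kappa1 = 9, kappa2 = 4)
  s <- bingham_noddi_signal(sch, p)
  expect_true(all(s[b0] == 1))
  expect_true(all(s > 0 & s <= 1))

  # pure CSF reduces to the ball
  pc <- bnoddi_params(1, 0.5)
  expect_equal(bingham_noddi_signal(sch, pc)[!b0],
               ball_signal(sch$bvals[!b0], 3.0e-9))

  # delta-ODF limit reduces to the stick
  pd <- bnoddi_params(0, 1, 0.7, 1.1, 0, kappa1 = 1e4, kappa2 = 1e4)
  st <- stick_signal(sch$bvecs[!b0, ], sch$bvals[!b0], bingham_frame(0.7, 1.1)[1, ])
  expect_equal(bingham_noddi_signal(sch, pd)[!b0], st, tolerance = 1e-3)

  # antipodal fibre axis
  p_neg <- bnoddi_params(0.2, 0.6, pi - 0.9, 0.3 + pi, -0.7, kappa1 = 9,
                         kappa2 = 4)  # frame of -mu
  expect_equal(bingham_noddi_signal(sch, p_neg), s, tolerance = 1e-10)

  # joint rotation of gradients and dispersion frame leaves the signal alone
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sch_rot <- make_scheme(sch$bvals, sch$bvecs %*% t(R))
  fr <- bingham_frame(0.9, 0.3, 0.7)
  fr_rot <- fr %*% t(R)
  mu_r <- fr_rot[1, ]
  p_rot <- bnoddi_params(0.2, 0.6, acos(mu_r[3]), atan2(mu_r[2], mu_r[1]),
                         0.7, kappa1 = 9, kappa2 = 4)
  # psi is preserved under rotations about z composed with the frame
  expect_equal(bingham_noddi_signal(sch_rot, p_rot), s, tolerance = 1e-9)

  expect_error(bingham_noddi_signal(make_scheme(numeric(0),
                                                matrix(0, 0, 3)), p),
               "empty")
})

test_that("convolution quadrature is converged: doubling changes < 1e-3", {
  sch <- four_shell_protocol(1)
  for (k1 in c(1, 16, 64)) {
    p <- bnoddi_params(0.1, 0.6, 0.9, 0.3, 0.7, kappa1 = k1, kappa2 = k1 / 2)
    s1 <- bingham_noddi_signal(sch, p)                      # default order
    s2 <- bingham_noddi_signal(sch, p, n_theta = 40, n_phi = 48)
    expect_lt(max(abs(s1 / s2 - 1)), 1e-3)
  }
})

test_that("tensor signal and FA/MD follow their definitions", {
  sch <- four_shell_protocol(2)
  b0 <- sch$bvals <= sch$b0_threshold
  lam <- 3.0e-3
  expect_equal(tensor_signal(sch, diag(rep(lam, 3)))[!b0],
               ball_signal(sch$bvals[!b0], 3.0e-9))
  expect_true(all(tensor_signal(sch, diag(rep(lam, 3)))[b0] == 1))

  mu <- c(1, 0, 0)
  D1 <- 1.7e-3 * outer(mu, mu)  # rank-1 along x
  expect_warning(ts <- tensor_signal(sch, D1), NA)
  expect_equal(ts[!b0], stick_signal(sch$bvecs[!b0, ], sch$bvals[!b0], mu))

  expect_warning(tensor_params(diag(c(1e-3, 1e-3, -1e-4))), "clamped")

  expect_equal(fa_md_from_eigenvalues(2e-3, 2e-3, 2e-3),
               list(FA = 0, MD = 2e-3))
  expect_equal(fa_md_from_eigenvalues(1.3e-3, 0, 0)$FA, 1)
  # hand-evaluated closed form
  fm <- fa_md_from_eigenvalues(1.7e-3, 0.2e-3, 0.2e-3)
  expect_equal(fm$MD, 0.7e-3)
  expect_equal(fm$FA, sqrt(1.5 * 1.5e-6 / 2.97e-6), tolerance = 1e-12)
  expect_equal(fm$FA, 0.87039, tolerance = 1e-4)
  expect_equal(fa_md_from_eigenvalues(0, 0, 0), list(FA = 0, MD = 0))
  expect_warning(fa_md_from_eigenvalues(1e-3, -1e-4, 0), "clamped")
})

test_that("derived scalar maps respect their definitions and limits", {
  p <- bnoddi_params(0, 1, kappa1 = 16, kappa2 = 2)
  m <- derive_noddi_maps(p)
  expect_equal(m[c("INVF", "ICVF", "ECVF")], list(INVF = 1, ICVF = 1, ECVF = 0))

  expect_equal(derive_noddi_maps(bnoddi_params(0.3, 0.5, kappa1 = 1))$ODI, 0.5)
  expect_lt(derive_noddi_maps(bnoddi_params(0, 1, kappa1 = 1e6))$ODI, 1e-5)
  expect_equal(derive_noddi_maps(bnoddi_params(0, 1, kappa1 = 0, kappa2 = 0))$ODI, 1)

  # ODI strictly decreasing in kappa1; ECVF + ICVF = 1 exactly
  odis <- vapply(c(0.5, 1, 2, 8, 32),
                 function(k) derive_noddi_maps(bnoddi_params(0.2, 0.4,
                                                             kappa1 = k))$ODI,
                 0)
  expect_true(all(diff(odis) < 0))
  for (f in c(0, 0.3, 0.9)) {
    m <- derive_noddi_maps(bnoddi_params(f, 0.4, kappa1 = 4, kappa2 = 1))
    expect_identical(m$ICVF + m$ECVF, 1)
    # Eq-style fraction conservation: f_csf + f_intra + f_extra = 1
    expect_equal(f + m$INVF + (1 - f) * (1 - 0.4), 1)
  }
  # the "nu" ICVF convention remains selectable
  m2 <- derive_noddi_maps(bnoddi_params(0.3, 0.4, kappa1 = 4), icvf = "nu")
  expect_equal(m2$ICVF, 0.4)
  expect_equal(m2$ECVF, 0.6)
})
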