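# Bingham-NODDI model fitting: box-constrained nonlinear least squares with
# multi-start, the diffusivities held fixed at their conventional values.

bnoddi_from_vector <- function(p) {
  bnoddi_params(f_csf = p[1], nu = p[2], theta = p[3], phi = p[4], psi = p[5],
                kappa1 = kappa_from_odi(p[6]), kappa2 = kappa_from_odi(p[6]) * p[7])
}

# Wrap fitted angles into canonical ranges: mu to the upper hemisphere,
# theta in [0, pi/2], phi in (-pi, pi], psi in [0, pi).
canonical_angles <- function(p) {
  fr <- bingham_frame(p[3], p[4], p[5])
  mu <- fr[1, ]
  if (mu[3] < 0) mu <- -mu  # antipodally equivalent
  theta <- acos(min(max(mu[3], -1), 1))
  phi <- atan2(mu[2], mu[1])
  # recover psi in the canonical frame at (theta, phi): e1 is psi-rotated
  fr0 <- bingham_frame(theta, phi, 0)
  psi <- atan2(sum(fr[2, ] * fr0[3, ]), sum(fr[2, ] * fr0[2, ])) %% pi
  c(p[1], p[2], theta, phi, psi, p[6], p[7])
}

#' Fit the Bingham-NODDI model
#'
#' Per-voxel box-constrained nonlinear least squares for the dispersed
#' three-compartment model ([bingham_noddi_signal()]) on normalized
#' attenuations, over the free parameters (f_csf, nu, theta, phi, psi, ODI,
#' beta-fraction); the diffusivities are fixed ([LAMBDA_CSF], [LAMBDA_PAR]).
#' A multi-start Levenberg-Marquardt strategy is used: the first eight starts
#' take their fibre axis from the principal eigenvector of a tensor fit and
#' scan a grid over the dispersion-plane angle psi (4 orientations) and the
#' dispersion anisotropy (2 levels) -- the objective is multimodal in that
#' subspace -- and any further starts are seeded quasi-random draws over the
#' parameter box; the lowest-objective solution wins (ties broken by start
#' index). Starts stop
#' early once a start reaches a near-perfect fit (MSE below `mse_stop`),
#' which makes noise-free fits cheap. Voxels whose fitted free-water
#' fraction exceeds 0.98 are flagged `degenerate`: the remaining parameters
#' are then unidentifiable (a pure-CSF voxel carries no tissue signal).
#'
#' @param scheme acquisition scheme with at least two distinct nonzero-b
#'   shells (the model is not identifiable from a single shell).
#' @param signals numeric vector (one voxel) or voxels x volumes matrix.
#' @param n_starts number of optimizer starts per voxel.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param tol relative convergence tolerance (ftol/ptol).
#' @param seed integer seed for the quasi-random restarts (deterministic).
#' @param mse_stop early-exit objective: stop launching further starts once a
#'   start's MSE falls below this.
#' @param n_theta,n_phi convolution quadrature orders used during fitting.
#' @param icvf ICVF definition passed to [derive_noddi_maps()].
#' @return object of class `bnoddi_fit`: per-voxel `params` (list of
#'   [bnoddi_params()]), a coefficient matrix (see [coef.bnoddi_fit()]),
#'   derived scalar columns (INVF, ICVF, ECVF, ODI, beta_fraction), fibre
#'   axes `mu` (n x 3), `mse`, `converged` and `degenerate` flags.
#' @export
fit_bingham_noddi <- function(scheme, signals, n_starts = 8, max_iter = 100,
                              tol = 1e-8, seed = 0, mse_stop = 1e-10,
                              n_theta = 28, n_phi = 32,
                              icvf = c("tissue", "nu")) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  icvf <- match.arg(icvf)
  tb <- shell_table(scheme)
  if (sum(tb$bval > 0) < 2)
    stopf(paste("at least two distinct nonzero b-value shells are required",
                "to fit the multi-compartment model (single-shell scheme given)"))
  signals <- as_signal_matrix(signals, length(scheme$bvals))
  n_vox <- nrow(signals)
  dwi <- scheme$bvals > scheme$b0_threshold
  s0 <- rowMeans(signals[, !dwi, drop = FALSE])
  dti <- suppressWarnings(fit_dti(scheme, signals))

  lower <- c(0, 0, -2 * pi, -2 * pi, -2 * pi, 1e-3, 0)
  upper <- c(1, 1, 2 * pi, 2 * pi, 2 * pi, 1, 1)
  n_structured <- min(n_starts, 8)
  rnd_starts <- with_local_seed(seed, {
    n_rnd <- max(n_starts - 8, 0)
    if (n_rnd == 0) NULL else
      cbind(stats::runif(n_rnd, 0.0, 0.6), stats::runif(n_rnd, 0.1, 0.9),
            stats::runif(n_rnd, 0, pi), stats::runif(n_rnd, -pi, pi),
            stats::runif(n_rnd, 0, pi), stats::runif(n_rnd, 0.05, 0.9),
            stats::runif(n_rnd, 0.05, 0.95))
  })
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                     ptol = tol)

  par_mat <- matrix(NA_real_, n_vox, 7)
  colnames(par_mat) <- c("f_csf", "nu", "theta", "phi", "psi", "ODI",
                         "beta_fraction")
  mse <- numeric(n_vox)
  converged <- logical(n_vox)
  params <- vector("list", n_vox)
  for (v in seq_len(n_vox)) {
    y <- signals[v, ] / s0[v]
    obj <- function(p) {
      bingham_noddi_signal(scheme, bnoddi_from_vector(p),
                           n_theta = n_theta, n_phi = n_phi) - y
    }
    e1 <- dti$evecs[[v]][, 1]
    th <- acos(min(max(abs(e1[3]), -1), 1))
    ph <- atan2(sign(e1[3] + (e1[3] == 0)) * e1[2],
                sign(e1[3] + (e1[3] == 0)) * e1[1])
    odi0 <- max(0.05, 1 - dti$FA[v]) * 0.5
    grid <- expand.grid(psi = (0:3) * pi / 4, bf = c(0.3, 0.8))
    structured <- cbind(0.1, 0.5, th, ph, grid$psi, odi0, grid$bf)
    starts <- rbind(structured[seq_len(n_structured), , drop = FALSE],
                    rnd_starts)
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      p0 <- pmin(pmax(starts[s, ], lower), upper)
      res <- tryCatch(
        minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = obj,
                           control = ctrl),
        error = function(e) NULL)
      if (is.null(res)) next
      o <- sum(res$fvec^2)
      if (is.null(best) || o < best$o - 1e-15) best <- list(o = o, res = res)
      if (best$o / length(y) < mse_stop) break
    }
    if (is.null(best)) stopf("all optimizer starts failed for voxel %d", v)
    # boundary polish: a fraction parameter stuck on a box face can shadow a
    # nearby interior optimum; pull each active bound inward once and refit
    for (j in c(1, 2, 7)) {  # f_csf, nu, beta_fraction
      if (best$o / length(y) < mse_stop) break
      pb <- stats::coef(best$res)
      at_lo <- pb[j] <= lower[j] + 1e-9
      at_hi <- pb[j] >= upper[j] - 1e-9
      if (!at_lo && !at_hi) next
      p0 <- pb
      p0[j] <- if (at_hi) upper[j] - 0.1 else lower[j] + 0.1
      res <- tryCatch(
        minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = obj,
                           control = ctrl),
        error = function(e) NULL)
      if (!is.null(res) && sum(res$fvec^2) < best$o - 1e-15)
        best <- list(o = sum(res$fvec^2), res = res)
    }
    p <- canonical_angles(stats::coef(best$res))
    par_mat[v, ] <- p
    mse[v] <- best$o / length(y)
    converged[v] <- best$res$info %in% 1:4
    params[[v]] <- bnoddi_from_vector(p)
  }
  derived <- t(vapply(params, function(p) {
    m <- derive_noddi_maps(p, icvf = icvf)
    c(m$INVF, m$ICVF, m$ECVF, m$ODI, m$beta_fraction)
  }, numeric(5)))
  colnames(derived) <- c("INVF", "ICVF", "ECVF", "ODI", "beta_fraction")
  mu <- t(vapply(params, function(p) bingham_frame(p$theta, p$phi)[1, ],
                 numeric(3)))
  structure(list(scheme = scheme, params = params, par = par_mat,
                 maps = derived, mu = mu, mse = mse, s0 = s0,
                 converged = converged,
                 degenerate = par_mat[, "f_csf"] >= 0.98,
                 icvf = icvf, n_theta = n_theta, n_phi = n_phi),
            class = "bnoddi_fit")
}

#' Coefficients of a Bingham-NODDI fit
#'
#' @param object a `bnoddi_fit`.
#' @param ... unused.
#' @return voxels x 7 matrix with columns f_csf, nu, theta, phi, psi, ODI,
#'   beta_fraction.
#' @export
coef.bnoddi_fit <- function(object, ...) object$par

#' @export
predict.bnoddi_fit <- function(object, scheme = object$scheme, ...) {
  t(vapply(object$params,
           function(p) bingham_noddi_signal(scheme, p,
                                            n_theta = object$n_theta,
                                            n_phi = object$n_phi),
           numeric(length(scheme$bvals))))
}

#' @export
fitted.bnoddi_fit <- function(object, ...) predict(object)

#' @export
residuals.bnoddi_fit <- function(object, signals = NULL, ...) {
  if (is.null(signals))
    stopf("supply the observed signals to compute bnoddi_fit residuals")
  signals <- as_signal_matrix(signals, length(object$scheme$bvals))
  signals / object$s0 - fitted(object)
}

#' @export
print.bnoddi_fit <- function(x, ...) {
  cat(sprintf("Bingham-NODDI fit: %d voxel(s), %d degenerate (f_csf >= 0.98)\n",
              nrow(x$par), sum(x$degenerate)))
  cat(sprintf("  MSE max %.3g; INVF %s; ODI %s\n", max(x$mse),
              paste(signif(range(x$maps[, "INVF"]), 3), collapse = " - "),
              paste(signif(range(x$maps[, "ODI"]), 3), collapse = " - ")))
  invisible(x)
}

#' @export
summary.bnoddi_fit <- function(object, ...) {
  data.frame(voxel = seq_len(nrow(object$par)), object$par, object$maps,
             mse = object$mse, converged = object$converged,
             degenerate = object$degenerate, check.names = FALSE)
}

#' Per-voxel mean-squared-error map of a fit
#'
#' Mean over volumes of the squared residual between the observed normalized
#' attenuation and the model prediction, for either model fit.
#'
#' @param fit a `dti_fit` or `bnoddi_fit`.
#' @param scheme the acquisition scheme of `signals` (defaults to the fit's).
#' @param signals observed signals, voxels x volumes (or vector).
#' @return numeric vector of per-voxel MSE values (unitless).
#' @export
mse_map <- function(fit, scheme = fit$scheme, signals) {
  signals <- as_signal_matrix(signals, length(scheme$bvals))
  if (nrow(signals) != length(fit$s0))
    stopf("shape mismatch: fit has %d voxels, signals %d",
          length(fit$s0), nrow(signals))
  pred <- predict(fit, scheme = scheme)
  rowMeans((signals / fit$s0 - pred)^2)
}
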