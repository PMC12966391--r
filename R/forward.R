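# Compartment forward models.
#
# Unit convention: b-values are s/mm^2 throughout; diffusivities are exposed
# in m^2/s (as usually quoted, e.g. 3.0e-9 m^2/s for free water) and converted
# internally to mm^2/s (x 1e6) so that b * lambda is dimensionless.

M2S_TO_MM2S <- 1e6

#' Fixed diffusivities of the multi-compartment tissue model
#'
#' Isotropic (free-water) diffusivity 3.0e-9 m^2/s and neurite intrinsic
#' parallel diffusivity 1.7e-9 m^2/s; both are held fixed during fitting.
#' @export
LAMBDA_CSF <- 3.0e-9

#' @rdname LAMBDA_CSF
#' @export
LAMBDA_PAR <- 1.7e-9

#' Ball compartment signal
#'
#' Isotropic Gaussian attenuation `exp(-b * lambda_iso)`, the free-water
#' (CSF) compartment.
#'
#' @param bval b-value(s), s/mm^2.
#' @param lambda_iso isotropic diffusivity, m^2/s.
#' @return attenuation(s) in (0, 1].
#' @examples
#' ball_signal(1000, 3.0e-9)  # exp(-3) ~ 0.0498
#' @export
ball_signal <- function(bval, lambda_iso = LAMBDA_CSF) {
  if (any(bval < 0)) stopf("negative b-value")
  if (any(lambda_iso <= 0)) stopf("lambda_iso must be positive")
  exp(-bval * lambda_iso * M2S_TO_MM2S)
}

check_unit <- function(v, what, tol = 1e-6) {
  if (abs(vnorm(v) - 1) > tol) stopf("%s must be a unit vector", what)
  v
}

#' Stick compartment signal
#'
#' Attenuation of an idealized zero-radius axon bundle along `mu`:
#' `exp(-b * lambda_par * (g . mu)^2)`. There is no signal decay
#' perpendicular to the stick.
#'
#' @param g gradient direction, unit 3-vector (or n x 3 matrix).
#' @param bval b-value(s), s/mm^2.
#' @param mu fibre axis, unit 3-vector.
#' @param lambda_par parallel diffusivity, m^2/s.
#' @return attenuation(s) in (0, 1].
#' @export
stick_signal <- function(g, bval, mu, lambda_par = LAMBDA_PAR) {
  if (any(bval < 0)) stopf("negative b-value")
  mu <- check_unit(mu, "mu")
  if (is.matrix(g)) {
    if (any(abs(row_norms(g) - 1) > 1e-6)) stopf("g rows must be unit vectors")
    ct2 <- as.vector(g %*% mu)^2
  } else {
    g <- check_unit(g, "g")
    ct2 <- sum(g * mu)^2
  }
  exp(-bval * lambda_par * M2S_TO_MM2S * ct2)
}

#' Zeppelin compartment signal
#'
#' Axially symmetric Gaussian attenuation with parallel and perpendicular
#' diffusivities: `exp(-b * (lambda_perp + (lambda_par - lambda_perp) *
#' (g . mu)^2))`. Reduces to the ball at `lambda_perp == lambda_par` and the
#' stick at `lambda_perp == 0`.
#'
#' @inheritParams stick_signal
#' @param lambda_perp perpendicular diffusivity, m^2/s; must not exceed
#'   `lambda_par`.
#' @export
zeppelin_signal <- function(g, bval, mu, lambda_par = LAMBDA_PAR, lambda_perp) {
  if (any(lambda_perp < 0) || any(lambda_perp > lambda_par))
    stopf("lambda_perp must lie in [0, lambda_par]")
  if (any(bval < 0)) stopf("negative b-value")
  mu <- check_unit(mu, "mu")
  ct2 <- if (is.matrix(g)) as.vector(g %*% mu)^2 else sum(check_unit(g, "g") * mu)^2
  exp(-bval * M2S_TO_MM2S * (lambda_perp + (lambda_par - lambda_perp) * ct2))
}

#' Tortuosity constraint on the extra-neurite perpendicular diffusivity
#'
#' The standard NODDI tortuosity model ties the extra-neurite zeppelin's
#' perpendicular diffusivity to the intra-neurite density:
#' `lambda_perp = lambda_par * (1 - nu)`.
#'
#' @param lambda_par parallel diffusivity, m^2/s.
#' @param nu relative intra-neurite fraction in \[0, 1\].
#' @return perpendicular diffusivity, m^2/s.
#' @export
tortuosity_perp <- function(lambda_par = LAMBDA_PAR, nu) {
  if (any(nu < 0 | nu > 1)) stopf("nu must lie in [0, 1]")
  lambda_par * (1 - nu)
}

#' Orthonormal dispersion frame from spherical angles
#'
#' Builds the (mu, e1, e2) triad of the Bingham distribution from the polar
#' angles of the fibre axis and the rotation `psi` of the dispersion plane
#' about it. `mu` is the dominant fibre orientation; `e1` and `e2` are the
#' primary and secondary dispersion axes.
#'
#' @param theta,phi polar and azimuthal angle of the fibre axis (radians).
#' @param psi rotation of the dispersion axes about the fibre axis (radians).
#' @return 3 x 3 matrix with rows mu, e1, e2.
#' @export
bingham_frame <- function(theta, phi, psi = 0) {
  mu <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  eth <- c(cos(theta) * cos(phi), cos(theta) * sin(phi), -sin(theta))
  eph <- c(-sin(phi), cos(phi), 0)
  e1 <- cos(psi) * eth + sin(psi) * eph
  e2 <- -sin(psi) * eth + cos(psi) * eph
  rbind(mu = mu, e1 = e1, e2 = e2)
}

check_frame <- function(frame) {
  if (!is.matrix(frame) || !all(dim(frame) == c(3, 3)))
    stopf("frame must be a 3 x 3 matrix with rows (mu, e1, e2)")
  if (max(abs(frame %*% t(frame) - diag(3))) > 1e-6)
    stopf("frame rows must be orthonormal")
  frame
}

# Quadrature for integrals of f(n) against the unnormalized Bingham density
# exp(-k1 (n.e1)^2 - k2 (n.e2)^2) over the sphere, assuming f antipodally
# symmetric (true of all diffusion kernels). Product rule in the dispersion
# frame with concentration-adapted node placement in both angles:
#   - polar angle theta (from mu): Gauss-Legendre nodes under a sinh stretch
#     whose inner scale is the peak width 1/sqrt(kappa1), so nodes cover all
#     scales from the peak to the equator; the grid is shared by every
#     azimuth;
#   - azimuth phi: Gauss-Legendre nodes on a quarter period under a sinh
#     stretch clustering at phi = pi/2, where the density concentrates when
#     kappa1 >> kappa2 (width ~ 1/sqrt(kappa1 - kappa2)), mirrored to the
#     four quadrants.
# Returns Q = n_theta * n_phi directions and weights such that
# sum(w * f(dirs)) approximates the integral of f times the density;
# sum(w) alone approximates the Bingham normalizer.
bingham_quadrature <- function(frame, kappa1, kappa2,
                               n_theta = 28, n_phi = 32) {
  if (kappa2 > kappa1 || kappa2 < 0) stopf("need kappa1 >= kappa2 >= 0")
  if (n_phi %% 4 != 0) stopf("n_phi must be a multiple of 4")
  w0 <- 1 / sqrt(max(kappa1, 1))
  cth <- asinh((pi / 2) / w0)
  gl <- pracma::gaussLegendre(n_theta, 0, 1)
  th <- w0 * sinh(gl$x * cth)
  wth <- gl$w * w0 * cth * cosh(gl$x * cth)   # includes d(theta)/du
  ct <- cos(th)
  st <- sin(th)

  wp <- 1 / sqrt(max(kappa1 - kappa2, 1))
  cph <- asinh((pi / 2) / wp)
  glp <- pracma::gaussLegendre(n_phi / 4, 0, 1)
  phq <- pi / 2 - wp * sinh(glp$x * cph)
  wph <- glp$w * wp * cph * cosh(glp$x * cph)
  phi <- c(phq, pi - phq, pi + phq, 2 * pi - phq)
  wphi <- rep(wph, 4)

  dirs <- matrix(0, n_theta * n_phi, 3)
  w <- numeric(n_theta * n_phi)
  for (k in seq_len(n_phi)) {
    ak <- kappa1 * cos(phi[k])^2 + kappa2 * sin(phi[k])^2
    idx <- (k - 1) * n_theta + seq_len(n_theta)
    dirs[idx, ] <- outer(ct, frame[1, ]) +
      outer(st * cos(phi[k]), frame[2, ]) + outer(st * sin(phi[k]), frame[3, ])
    # 2x: the theta integral runs over one hemisphere only
    w[idx] <- 2 * wphi[k] * wth * exp(-ak * st^2) * st
  }
  list(dirs = dirs, w = w)
}

# Bingham normalization constant: the azimuthal integral reduces exactly to
# a modified Bessel function, leaving one smooth 1-D integral:
# Z = 4 pi int_0^1 exp(-s (k1+k2)/2) I0(s (k1-k2)/2) dt,  s = 1 - t^2.
# Adaptive quadrature makes this accurate to ~1e-10 for any concentration.
bingham_normalizer <- function(kappa1, kappa2) {
  if (kappa2 > kappa1 || kappa2 < 0) stopf("need kappa1 >= kappa2 >= 0")
  sm <- (kappa1 + kappa2) / 2
  df <- (kappa1 - kappa2) / 2
  f <- function(t) {
    s <- 1 - t^2
    # scaled Bessel keeps the integrand finite for large concentrations
    exp(-s * sm + s * df) * besselI(s * df, 0, expon.scaled = TRUE)
  }
  4 * pi * stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value
}

#' Bingham orientation distribution function
#'
#' Antipodally symmetric density on the sphere,
#' proportional to `exp(-kappa1 (n . e1)^2 - kappa2 (n . e2)^2)`, normalized
#' numerically so that it integrates to one over the whole sphere. The mode
#' is the fibre axis `mu` (first row of `frame`); `kappa1 >= kappa2 >= 0`
#' control the concentration about the two dispersion axes (equal
#' concentrations give a Watson distribution; both zero gives the uniform
#' density 1/(4 pi)).
#'
#' @param n unit direction(s): 3-vector or n x 3 matrix.
#' @param frame orthonormal triad from [bingham_frame()].
#' @param kappa1,kappa2 concentration parameters, `kappa1 >= kappa2 >= 0`.
#' @return density value(s), 1/steradian.
#' @export
bingham_odf <- function(n, frame, kappa1, kappa2) {
  check_frame(frame)
  if (kappa2 > kappa1 || kappa2 < 0) stopf("need kappa1 >= kappa2 >= 0")
  if (!is.matrix(n)) n <- matrix(n, 1)
  z <- bingham_normalizer(kappa1, kappa2)
  u1 <- as.vector(n %*% frame[2, ])
  u2 <- as.vector(n %*% frame[3, ])
  exp(-kappa1 * u1^2 - kappa2 * u2^2) / z
}

#' Bingham-NODDI model parameters
#'
#' Parameter set of the three-compartment dispersed-neurite signal model: a
#' free-water ball with fraction `f_csf`, plus a tissue compartment (fraction
#' `1 - f_csf`) split between intra-neurite sticks (relative fraction `nu`)
#' and an extra-neurite tortuosity-constrained zeppelin (`1 - nu`), both
#' convolved over a Bingham orientation distribution. The implied global
#' fractions are `f_intra = (1 - f_csf) * nu` and
#' `f_extra = (1 - f_csf) * (1 - nu)`, which sum with `f_csf` to one.
#' Diffusivities are fixed at the conventional values (see [LAMBDA_CSF]).
#'
#' @param f_csf free-water volume fraction in \[0, 1\].
#' @param nu relative intra-neurite fraction in \[0, 1\].
#' @param theta,phi,psi dispersion-frame angles, see [bingham_frame()].
#' @param kappa1,kappa2 Bingham concentrations, `kappa1 >= kappa2 >= 0`.
#' @param lambda_csf,lambda_par fixed diffusivities, m^2/s.
#' @return object of class `bnoddi_params`.
#' @export
bnoddi_params <- function(f_csf, nu, theta = 0, phi = 0, psi = 0,
                          kappa1 = 16, kappa2 = 0,
                          lambda_csf = LAMBDA_CSF, lambda_par = LAMBDA_PAR) {
  if (f_csf < 0 || f_csf > 1) stopf("f_csf must lie in [0, 1]")
  if (nu < 0 || nu > 1) stopf("nu must lie in [0, 1]")
  if (kappa2 > kappa1 || kappa2 < 0) stopf("need kappa1 >= kappa2 >= 0")
  structure(list(f_csf = f_csf, nu = nu, theta = theta, phi = phi, psi = psi,
                 kappa1 = kappa1, kappa2 = kappa2,
                 lambda_csf = lambda_csf, lambda_par = lambda_par),
            class = "bnoddi_params")
}

#' @export
print.bnoddi_params <- function(x, ...) {
  m <- derive_noddi_maps(x)
  cat(sprintf(paste0("Bingham-NODDI parameters: f_csf = %.3f, nu = %.3f, ",
                     "kappa1 = %.3g, kappa2 = %.3g\n  (ODI = %.3f, ",
                     "beta-fraction = %.3f, INVF = %.3f)\n"),
              x$f_csf, x$nu, x$kappa1, x$kappa2, m$ODI, m$beta_fraction,
              m$INVF))
  invisible(x)
}

#' Bingham-NODDI composite signal
#'
#' Per-volume attenuation of the three-compartment model: the free-water ball
#' plus the Bingham-ODF spherical convolution of the intra-neurite stick and
#' the tortuosity-constrained extra-neurite zeppelin,
#' with `lambda_perp = lambda_par * (1 - nu)` ([tortuosity_perp()]).
#' The convolution is evaluated by the adaptive product quadrature of
#' [bingham_odf()]; unweighted (b = 0) volumes return exactly 1.
#'
#' @param scheme an [make_scheme()] acquisition scheme.
#' @param params a [bnoddi_params()] object.
#' @param n_theta,n_phi quadrature orders of the spherical convolution.
#' @return numeric vector of attenuations, one per volume.
#' @export
bingham_noddi_signal <- function(scheme, params, n_theta = 28, n_phi = 32) {
  stopifnot(inherits(scheme, "acquisition_scheme"),
            inherits(params, "bnoddi_params"))
  if (length(scheme$bvals) == 0) stopf("empty acquisition scheme")
  frame <- bingham_frame(params$theta, params$phi, params$psi)
  quad <- bingham_quadrature(frame, params$kappa1, params$kappa2,
                             n_theta, n_phi)
  p <- quad$w / sum(quad$w)
  b <- scheme$bvals
  lp <- params$lambda_par * M2S_TO_MM2S
  lperp <- lp * (1 - params$nu)
  bC2 <- b * (scheme$bvecs %*% t(quad$dirs))^2  # b_i (g_i . n_q)^2
  stick <- exp(-lp * bC2)
  zep <- exp(-lperp * b) * exp(-(lp - lperp) * bC2)
  kern <- params$nu * stick + (1 - params$nu) * zep
  s <- params$f_csf * exp(-b * params$lambda_csf * M2S_TO_MM2S) +
    (1 - params$f_csf) * as.vector(kern %*% p)
  s[b <= scheme$b0_threshold] <- 1
  s
}

#' Diffusion tensor parameters
#'
#' Wraps a symmetric 3 x 3 diffusion tensor (mm^2/s) with its
#' eigen-decomposition: eigenvalues sorted descending and the matching unit
#' eigenvectors. Slightly negative eigenvalues (non-physical) are clamped to
#' zero with a warning.
#'
#' @param D symmetric 3 x 3 matrix, mm^2/s.
#' @return object of class `tensor_params` with elements `D`, `evals`,
#'   `evecs` (columns are eigenvectors, ordered as `evals`).
#' @export
tensor_params <- function(D) {
  D <- as.matrix(D)
  if (!all(dim(D) == c(3, 3)) || max(abs(D - t(D))) > 1e-10 * max(1, max(abs(D))))
    stopf("D must be a symmetric 3 x 3 matrix")
  D <- (D + t(D)) / 2
  e <- eigen(D, symmetric = TRUE)  # descending eigenvalues
  if (any(e$values < -1e-12 * max(1, max(abs(e$values))))) {
    warnf("negative tensor eigenvalue(s) clamped to 0")
  }
  evals <- pmax(e$values, 0)
  structure(list(D = D, evals = evals, evecs = e$vectors),
            class = "tensor_params")
}

#' Diffusion tensor signal
#'
#' Monoexponential tensor attenuation `exp(-b g' D g)` per volume; unweighted
#' volumes return exactly 1. Non-positive-semidefinite tensors are clamped
#' (negative eigenvalues to zero) with a warning.
#'
#' @param scheme an [make_scheme()] acquisition scheme.
#' @param D a [tensor_params()] object or a symmetric 3 x 3 matrix (mm^2/s).
#' @return numeric vector of attenuations, one per volume.
#' @export
tensor_signal <- function(scheme, D) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (!inherits(D, "tensor_params")) D <- tensor_params(D)
  Dm <- D$evecs %*% diag(D$evals) %*% t(D$evecs)
  q <- rowSums((scheme$bvecs %*% Dm) * scheme$bvecs)
  s <- exp(-scheme$bvals * q)
  s[scheme$bvals <= scheme$b0_threshold] <- 1
  s
}

#' Fractional anisotropy and mean diffusivity from tensor eigenvalues
#'
#' `MD = (l1 + l2 + l3) / 3` and
#' `FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2))`; the FA of the
#' zero tensor is defined as 0. Vectorized over voxels; negative eigenvalues
#' are clamped to zero with a warning.
#'
#' @param l1,l2,l3 eigenvalues (mm^2/s), scalars or equal-length vectors.
#' @return list with numeric elements `FA` (unitless) and `MD` (mm^2/s).
#' @export
fa_md_from_eigenvalues <- function(l1, l2, l3) {
  ev <- cbind(l1, l2, l3)
  if (any(ev < 0)) {
    warnf("negative eigenvalue(s) clamped to 0")
    ev[ev < 0] <- 0
  }
  md <- rowMeans(ev)
  num <- rowSums((ev - md)^2)
  den <- rowSums(ev^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  list(FA = as.numeric(fa), MD = as.numeric(md))
}

#' Scalar maps derived from Bingham-NODDI parameters
#'
#' Derives the scalar microstructure indices from a fitted (or specified)
#' parameter set:
#' \describe{
#'   \item{INVF}{intra-neurite volume fraction `(1 - f_csf) * nu`.}
#'   \item{ICVF}{intra-cellular volume fraction. Definition `"tissue"`
#'     (default) takes the non-free-water fraction `1 - f_csf`;
#'     definition `"nu"` takes the classic relative neurite density `nu`.}
#'   \item{ECVF}{extra-cellular volume fraction, always `1 - ICVF`.}
#'   \item{ODI}{orientation dispersion index `(2/pi) * atan(1 / kappa1)`,
#'     1 for the uniform ODF (`kappa1 = 0`), approaching 0 for perfectly
#'     coherent fibres.}
#'   \item{beta_fraction}{dispersion anisotropy `kappa2 / kappa1` (0 when
#'     `kappa1 = 0`).}
#' }
#'
#' @param params a [bnoddi_params()] object.
#' @param icvf `"tissue"` or `"nu"`, see above.
#' @return named list of scalars.
#' @export
derive_noddi_maps <- function(params, icvf = c("tissue", "nu")) {
  stopifnot(inherits(params, "bnoddi_params"))
  icvf <- match.arg(icvf)
  icvf_val <- if (icvf == "tissue") 1 - params$f_csf else params$nu
  odi <- if (params$kappa1 == 0) 1 else (2 / pi) * atan(1 / params$kappa1)
  bfrac <- if (params$kappa1 == 0) 0 else params$kappa2 / params$kappa1
  list(INVF = (1 - params$f_csf) * params$nu,
       ICVF = icvf_val,
       ECVF = 1 - icvf_val,
       ODI = odi,
       beta_fraction = bfrac,
       kappa2 = params$kappa2)
}

#' Concentration parameter from orientation dispersion index
#'
#' Inverse of the ODI mapping `ODI = (2/pi) atan(1/kappa)`:
#' `kappa = 1 / tan(pi ODI / 2)`, for ODI in (0, 1].
#'
#' @param odi dispersion index value(s) in (0, 1].
#' @return concentration parameter(s) `kappa >= 0`.
#' @export
kappa_from_odi <- function(odi) {
  stopifnot(all(odi > 0 & odi <= 1))
  1 / tan(pi * odi / 2)
}
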