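# Diffusion tensor estimation by log-linear least squares.

# 6-column b-matrix design for ln(S/S0) = -b g' D g, weighted volumes only.
dti_design <- function(scheme) {
  dwi <- scheme$bvals > scheme$b0_threshold
  g <- scheme$bvecs[dwi, , drop = FALSE]
  b <- scheme$bvals[dwi]
  X <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                  2 * g[, 2] * g[, 3])
  colnames(X) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  list(X = X, dwi = dwi, b = b)
}

as_signal_matrix <- function(signals, n_vol) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  signals <- as.matrix(signals)
  if (ncol(signals) != n_vol)
    stopf("signals have %d volumes but the scheme has %d",
          ncol(signals), n_vol)
  signals
}

#' Fit the diffusion tensor model
#'
#' Per-voxel log-linear least-squares estimate of the diffusion tensor from
#' multi-shell signals: the unweighted (b = 0) volumes are averaged into S0,
#' and `ln(S/S0)` of the weighted volumes is regressed on the 6-element
#' b-matrix design. Eigenvalues are sorted descending; negative eigenvalues
#' are clamped to zero and the voxel flagged. Non-positive signals are
#' floored at 1e-10 before the log, with a warning.
#'
#' @param scheme an [make_scheme()] acquisition scheme; it must contain at
#'   least one unweighted volume and at least six weighted volumes spanning
#'   six linearly independent b-matrix components.
#' @param signals numeric vector (one voxel) or voxels x volumes matrix of
#'   signal intensities (any common scale; normalization is internal).
#' @param weighted if `TRUE`, iterate one weighted least-squares pass with
#'   the predicted signals as weights (WLS); default ordinary LS, matching
#'   the usual tensor-fitting default.
#' @return object of class `dti_fit` with per-voxel elements: `evals`
#'   (n x 3, mm^2/s, descending), `evecs` (list of 3 x 3 eigenvector
#'   matrices, columns matching `evals`), `FA`, `MD`, `mse` (mean squared
#'   residual on normalized attenuation), `clamped` (negative-eigenvalue
#'   flag), plus the scheme and S0.
#' @examples
#' sch <- four_shell_protocol(1)
#' D <- diag(c(1.7e-3, 0.2e-3, 0.2e-3))
#' fit <- fit_dti(sch, tensor_signal(sch, D))
#' coef(fit)
#' @export
fit_dti <- function(scheme, signals, weighted = FALSE) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  signals <- as_signal_matrix(signals, length(scheme$bvals))
  des <- dti_design(scheme)
  if (sum(!des$dwi) < 1) stopf("design deficiency: no unweighted (b = 0) volume")
  if (nrow(des$X) < 6)
    stopf("design deficiency: only %d weighted volumes (need >= 6)", nrow(des$X))
  qrX <- qr(des$X)
  if (qrX$rank < 6)
    stopf("design deficiency: b-matrix rank %d < 6 (collinear directions)",
          qrX$rank)
  if (any(signals <= 0)) {
    warnf("non-positive signal(s) floored at 1e-10 before log")
    signals[signals <= 0] <- 1e-10
  }
  n_vox <- nrow(signals)
  s0 <- rowMeans(signals[, !des$dwi, drop = FALSE])
  y <- log(pmax(signals[, des$dwi, drop = FALSE] / s0, 1e-10))
  beta <- t(qr.coef(qrX, t(y)))  # n_vox x 6
  if (weighted) {
    for (v in seq_len(n_vox)) {
      w <- exp(as.vector(des$X %*% beta[v, ]))  # predicted attenuations
      beta[v, ] <- qr.coef(qr(des$X * w), y[v, ] * w)
    }
  }
  evals <- matrix(0, n_vox, 3)
  evecs <- vector("list", n_vox)
  clamped <- logical(n_vox)
  for (v in seq_len(n_vox)) {
    D <- matrix(c(beta[v, 1], beta[v, 4], beta[v, 5],
                  beta[v, 4], beta[v, 2], beta[v, 6],
                  beta[v, 5], beta[v, 6], beta[v, 3]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    clamped[v] <- any(e$values < 0)
    evals[v, ] <- pmax(e$values, 0)
    evecs[[v]] <- e$vectors
  }
  famd <- fa_md_from_eigenvalues(evals[, 1], evals[, 2], evals[, 3])
  fit <- structure(list(scheme = scheme, evals = evals, evecs = evecs,
                        FA = famd$FA, MD = famd$MD, s0 = s0,
                        clamped = clamped, weighted = weighted),
                   class = "dti_fit")
  fit$mse <- rowMeans((fitted(fit) - signals / s0)^2)
  fit
}

#' @export
coef.dti_fit <- function(object, ...) {
  out <- cbind(object$evals, object$FA, object$MD)
  colnames(out) <- c("l1", "l2", "l3", "FA", "MD")
  out
}

# Predicted normalized attenuations (voxels x volumes) for a dti_fit,
# optionally under a different acquisition scheme.
#' @export
predict.dti_fit <- function(object, scheme = object$scheme, ...) {
  n_vox <- nrow(object$evals)
  out <- matrix(0, n_vox, length(scheme$bvals))
  for (v in seq_len(n_vox)) {
    D <- object$evecs[[v]] %*% diag(object$evals[v, ]) %*% t(object$evecs[[v]])
    out[v, ] <- tensor_signal(scheme, tensor_params(D))
  }
  out
}

#' @export
fitted.dti_fit <- function(object, ...) predict(object)

#' @export
residuals.dti_fit <- function(object, signals = NULL, ...) {
  if (is.null(signals))
    stopf("supply the observed signals to compute dti_fit residuals")
  signals <- as_signal_matrix(signals, length(object$scheme$bvals))
  signals / object$s0 - fitted(object)
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf("Diffusion tensor fit (%s log-linear LS): %d voxel(s)\n",
              if (x$weighted) "weighted" else "ordinary", nrow(x$evals)))
  cat(sprintf("  FA: %s   MD: %s mm^2/s   MSE: %s\n",
              paste(signif(range(x$FA), 3), collapse = " - "),
              paste(signif(range(x$MD), 3), collapse = " - "),
              signif(max(x$mse), 3)))
  invisible(x)
}

#' @export
summary.dti_fit <- function(object, ...) {
  data.frame(voxel = seq_len(nrow(object$evals)),
             l1 = object$evals[, 1], l2 = object$evals[, 2],
             l3 = object$evals[, 3], FA = object$FA, MD = object$MD,
             mse = object$mse, clamped = object$clamped)
}
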