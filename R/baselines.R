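#' Classical minimum-norm inverse solvers
#'
#' Closed-form solutions of the Tikhonov-regularized inverse problem
#' \deqn{\hat S = \arg\min_S \tfrac12\|Y - LS\|_F^2 + \lambda \|S\|_2^2,}
#' whose minimizer is \eqn{\hat S = L^T (L L^T + \lambda I)^{-1} Y}. sLORETA
#' standardizes the minimum-norm estimate by the resolution-matrix variance;
#' dSPM normalizes it by the noise-projected standard deviation. All solvers
#' are linear in Y.
#'
#' @name baselines
NULL

#' Minimum-norm inverse operator
#'
#' @param lf A `leadfield` or bare C x N matrix.
#' @param lambda Regularization weight (>= 0).
#' @return An `inverse_operator`: list with `G` (N x C), `lambda`, `method`,
#'   and `R_diag` (diagonal of the resolution/variance term
#'   \eqn{L^T (L L^T + \lambda I)^{-1} L}, used by sLORETA).
#' @export
mne_operator <- function(lf, lambda) {
  L <- if (inherits(lf, "leadfield")) lf$L else as.matrix(lf)
  if (lambda < 0) stop("`lambda` must be >= 0")
  K <- tcrossprod(L) # C x C
  diag(K) <- diag(K) + lambda
  Kinv_L <- tryCatch(solve(K, L), error = function(e) {
    stop("gram matrix is singular at this lambda; use lambda > 0", call. = FALSE)
  })
  G <- t(Kinv_L) # N x C = L' (LL' + lambda I)^-1
  R_diag <- colSums(L * Kinv_L) # diag(L' Kinv L)
  structure(list(G = G, lambda = lambda, method = "mne", R_diag = R_diag),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %s, %d sources x %d channels, lambda=%g\n",
              x$method, nrow(x$G), ncol(x$G), x$lambda))
  invisible(x)
}

#' Apply an inverse operator
#'
#' @param op An [mne_operator()].
#' @param Y C x K measurement matrix (or length-C vector).
#' @return N x K source estimate (vector for K = 1).
#' @export
apply_inverse <- function(op, Y) {
  Y <- if (is.null(dim(Y))) matrix(Y, ncol = 1) else as.matrix(Y)
  out <- op$G %*% Y
  if (ncol(out) == 1) drop(out) else out
}

#' sLORETA standardized source map
#'
#' Minimum-norm estimate standardized by the resolution-derived variance:
#' per region, \eqn{\hat s_i^2 / R_{ii}} with \eqn{R = L^T(LL^T+\lambda I)^{-1}L}.
#' Nonnegative by construction; for noiseless single-dipole data its argmax
#' sits at the true source (zero localization error), for any lambda.
#'
#' @inheritParams mne_operator
#' @param Y Measurements (C x K or length-C).
#' @return N x K matrix (or vector) of standardized power values.
#' @export
sloreta_solve <- function(lf, Y, lambda) {
  op <- mne_operator(lf, lambda)
  if (any(op$R_diag <= 0)) {
    stop("zero resolution variance for some region; leadfield column degenerate")
  }
  s <- apply_inverse(op, Y)
  s <- as_snapshot_matrix(s)
  out <- s^2 / op$R_diag
  if (ncol(out) == 1) drop(out) else out
}

#' dSPM noise-normalized source map
#'
#' Minimum-norm estimate divided by its noise standard deviation
#' \eqn{\sqrt{\mathrm{diag}(G \Sigma G^T)}} under noise covariance
#' \eqn{\Sigma}.
#'
#' @inheritParams sloreta_solve
#' @param noise_cov C x C symmetric positive-definite noise covariance.
#' @return N x K matrix (or vector) of noise-normalized amplitudes.
#' @export
dspm_solve <- function(lf, Y, lambda, noise_cov) {
  op <- mne_operator(lf, lambda)
  noise_cov <- as.matrix(noise_cov)
  if (!isSymmetric(unname(noise_cov), tol = 1e-8)) stop("`noise_cov` must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`noise_cov` must be positive definite")
  v <- rowSums((op$G %*% noise_cov) * op$G) # diag(G Sigma G')
  if (any(v <= 0)) stop("zero noise variance for some region (zero operator row)")
  s <- as_snapshot_matrix(apply_inverse(op, Y))
  out <- s / sqrt(v)
  if (ncol(out) == 1) drop(out) else out
}

#' SNR-transformation fusion of EEG and MEG
#'
#' Converts both modalities to a common signal-to-noise scale by whitening:
#' each modality's measurement rows and leadfield rows are divided by that
#' modality's noise standard deviation (so the transformed noise has unit
#' variance per channel), then the two systems are row-stacked. Any inverse
#' solver can then treat the stacked system as a single measurement.
#'
#' @param Y_eeg,Y_meg Measurements (C x K or length-C vectors).
#' @param lf_eeg,lf_meg Leadfields (objects or matrices).
#' @param noise_sd_eeg,noise_sd_meg Per-modality noise standard deviations
#'   (> 0).
#' @return List with `Y` ((C_eeg + C_meg) x K) and `L` (stacked whitened
#'   leadfield), ready for [mne_operator()] / [sloreta_solve()] /
#'   [dspm_solve()] (the whitened noise covariance is the identity).
#' @export
snr_fuse <- function(Y_eeg, lf_eeg, noise_sd_eeg, Y_meg, lf_meg, noise_sd_meg) {
  if (noise_sd_eeg <= 0 || noise_sd_meg <= 0) stop("noise SDs must be > 0")
  Le <- if (inherits(lf_eeg, "leadfield")) lf_eeg$L else as.matrix(lf_eeg)
  Lm <- if (inherits(lf_meg, "leadfield")) lf_meg$L else as.matrix(lf_meg)
  Ye <- as_snapshot_matrix(Y_eeg); Ym <- as_snapshot_matrix(Y_meg)
  if (nrow(Ye) != nrow(Le) || nrow(Ym) != nrow(Lm)) {
    stop("measurement/leadfield channel counts disagree")
  }
  list(
    Y = rbind(Ye / noise_sd_eeg, Ym / noise_sd_meg),
    L = rbind(Le / noise_sd_eeg, Lm / noise_sd_meg)
  )
}

#' Default regularization weight
#'
#' \eqn{\lambda = \mathrm{tr}(LL^T)/C \cdot 1/\mathrm{SNR}} when the linear
#' SNR is known, else 1e-2 of the mean sensor power.
#'
#' @param lf Leadfield (object or matrix).
#' @param snr_db Known SNR in dB, or `NULL`.
#' @return Scalar lambda.
#' @export
default_lambda <- function(lf, snr_db = NULL) {
  L <- if (inherits(lf, "leadfield")) lf$L else as.matrix(lf)
  base <- sum(L^2) / nrow(L) # trace(LL')/C
  if (is.null(snr_db)) 1e-2 * base else base / 10^(snr_db / 10)
}
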