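#' Sensor arrays
#'
#' @param modality `"eeg"` or `"meg"`.
#' @param positions C x 3 sensor coordinates (meters).
#' @param orientations C x 3 unit sensor normals; required for MEG
#'   (magnetometer pickup direction), ignored for EEG.
#' @return A `sensor_array` object.
#' @export
sensor_array <- function(modality = c("eeg", "meg"), positions, orientations = NULL) {
  modality <- match.arg(modality)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 1) stop("positions must be C x 3 with C >= 1")
  if (modality == "meg") {
    if (is.null(orientations)) stop("MEG sensors need `orientations`")
    orientations <- as.matrix(orientations)
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-9)) stop("MEG orientations must be unit-norm")
  }
  structure(
    list(modality = modality, positions = positions, orientations = orientations),
    class = "sensor_array"
  )
}

#' Near-uniform sensor coverage of a sphere
#'
#' Places `n` points on a sphere of radius `radius_m` along a Fibonacci
#' (golden-angle) spiral — the standard way to get an approximately uniform,
#' symmetry-free layout at any count. For MEG arrays the sensor normal is the
#' outward radial direction (magnetometers measuring the radial field).
#'
#' @inheritParams sensor_array
#' @param n Number of sensors.
#' @param radius_m Shell radius in meters.
#' @return A `sensor_array`.
#' @export
fibonacci_sensors <- function(n, radius_m, modality = c("eeg", "meg")) {
  modality <- match.arg(modality)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  p <- cbind(r * cos(th), r * sin(th), z)
  sensor_array(modality, p * radius_m,
               orientations = if (modality == "meg") p else NULL)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %s, %d channels\n", toupper(x$modality), nrow(x$positions)))
  invisible(x)
}

#' EEG leadfield of an analytic dipole model
#'
#' Potential of a current dipole in an unbounded homogeneous conductor,
#' \deqn{V(r) = \frac{1}{4\pi\sigma} \frac{q \cdot (r - r_0)}{\|r - r_0\|^3},}
#' evaluated at each electrode and re-referenced to the channel average.
#' Each column is the potential pattern of a unit dipole (moment along the
#' source-space orientation). The model is sensitive to radial and tangential
#' dipole components alike, and every column sums to zero across channels
#' (average reference).
#'
#' @param space A `source_space`.
#' @param sensors An EEG `sensor_array`; electrodes must not coincide with
#'   sources.
#' @param conductivity Medium conductivity in S/m (default 0.33, soft tissue).
#' @return A `leadfield` object: `L` (C x N, volts per unit dipole moment),
#'   `modality`, plus the generating space/sensors.
#' @export
eeg_leadfield <- function(space, sensors, conductivity = 0.33) {
  if (sensors$modality != "eeg") stop("`sensors` must be an EEG array")
  src <- space$positions
  ori <- space$orientations
  el <- sensors$positions
  C <- nrow(el); N <- nrow(src)
  L <- matrix(0, C, N)
  for (n in seq_len(N)) {
    a <- el - matrix(src[n, ], C, 3, byrow = TRUE)
    a3 <- rowSums(a^2)^1.5
    if (any(a3 < 1e-18)) stop(sprintf("electrode coincides with source %d", n))
    L[, n] <- (a %*% ori[n, ]) / (4 * pi * conductivity * a3)
  }
  L <- sweep(L, 2, colMeans(L)) # average reference
  new_leadfield(L, "eeg", space, sensors)
}

#' MEG leadfield of the single-sphere conductor model
#'
#' Magnetic field of a current dipole inside a spherical conductor (Sarvas
#' closed form), projected on each magnetometer normal. The field outside a
#' sphere is independent of the conductivity profile, and a purely radial
#' dipole produces exactly zero field — the physical root of the EEG/MEG
#' complementarity this package exploits.
#'
#' @param space A `source_space` (sphere centered at the origin).
#' @param sensors A MEG `sensor_array` strictly outside the source sphere.
#' @return A `leadfield` object (`L` in tesla per unit dipole moment).
#' @export
meg_leadfield <- function(space, sensors) {
  if (sensors$modality != "meg") stop("`sensors` must be a MEG array")
  src <- space$positions
  ori <- space$orientations
  sens <- sensors$positions
  nrm <- sensors$orientations
  rs <- sqrt(rowSums(sens^2))
  if (any(rs <= space$radius_m + 1e-12)) stop("MEG sensors must lie outside the conductor sphere")
  mu0 <- 4e-7 * pi
  C <- nrow(sens); N <- nrow(src)
  L <- matrix(0, C, N)
  for (n in seq_len(N)) {
    r0 <- src[n, ]
    q <- ori[n, ]
    qxr0 <- c(
      q[2] * r0[3] - q[3] * r0[2],
      q[3] * r0[1] - q[1] * r0[3],
      q[1] * r0[2] - q[2] * r0[1]
    )
    for (ci in seq_len(C)) {
      r <- sens[ci, ]
      a_v <- r - r0
      a <- sqrt(sum(a_v^2))
      rr <- sqrt(sum(r^2))
      ar <- sum(a_v * r)
      FF <- a * (rr * a + rr^2 - sum(r0 * r))
      gF <- (a^2 / rr + ar / a + 2 * a + 2 * rr) * r - (a + 2 * rr + ar / a) * r0
      B <- mu0 / (4 * pi * FF^2) * (FF * qxr0 - sum(qxr0 * r) * gF)
      L[ci, n] <- sum(B * nrm[ci, ])
    }
  }
  new_leadfield(L, "meg", space, sensors)
}

new_leadfield <- function(L, modality, space = NULL, sensors = NULL) {
  if (any(!is.finite(L))) stop("leadfield contains non-finite entries")
  structure(
    list(L = L, modality = modality, space = space, sensors = sensors),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %s, %d channels x %d sources\n",
              toupper(x$modality), nrow(x$L), ncol(x$L)))
  invisible(x)
}

#' Apply the forward equation Y = L S
#'
#' Noiseless projection of source amplitudes to sensor space.
#'
#' @param lf A `leadfield` (or bare C x N matrix).
#' @param S N x K source amplitude matrix (or length-N vector, K = 1).
#' @return C x K matrix of sensor measurements.
#' @export
project_forward <- function(lf, S) {
  L <- if (inherits(lf, "leadfield")) lf$L else as.matrix(lf)
  S <- if (is.null(dim(S))) matrix(S, ncol = 1) else as.matrix(S)
  if (ncol(L) != nrow(S)) {
    stop(sprintf("shape mismatch: leadfield has %d sources, S has %d rows",
                 ncol(L), nrow(S)))
  }
  L %*% S
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise power is scaled so that \eqn{10 \log_{10}(P_{signal}/P_{noise})}
#' equals `snr_db`, with powers taken as mean squared amplitude over all
#' entries of `Y`. Deterministic given `seed`.
#'
#' @param Y Noiseless measurement matrix (nonzero).
#' @param snr_db Target SNR in decibels.
#' @param seed Integer seed for the noise draw.
#' @return Matrix of the same shape, `Y` plus noise; attribute `snr_db` kept.
#' @export
add_noise_at_snr <- function(Y, snr_db, seed) {
  Y <- as.matrix(Y)
  p_sig <- mean(Y^2)
  if (!is.finite(snr_db)) stop("`snr_db` must be finite")
  if (p_sig == 0) stop("SNR undefined: `Y` is identically zero")
  p_noise <- p_sig / 10^(snr_db / 10)
  noise <- withr_seed(seed, matrix(stats::rnorm(length(Y), sd = sqrt(p_noise)),
                                   nrow(Y), ncol(Y)))
  out <- Y + noise
  attr(out, "snr_db") <- snr_db
  out
}
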