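test_that("MNE operator matches the Tikhonov closed form from both factorizations", {
  set.seed(6)
  L <- matrix(rnorm(12 * 30), 12, 30)
  lam <- 0.5
  op <- mne_operator(L, lam)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  S1 <- op$G %*% Y
  # independent route: (L'L + lambda I)^-1 L' Y (identical minimizer)
  S2 <- solve(crossprod(L) + lam * diag(30), crossprod(L, Y))
  expect_equal(S1, S2, tolerance = 1e-8)

  # identity system, lambda = 0 reproduces the data
  opI <- mne_operator(diag(4), 0)
  y <- rnorm(4)
  expect_equal(apply_inverse(opI, y), y, tolerance = 1e-12)

  # strong regularization shrinks to zero
  op_big <- mne_operator(L, 1e12)
  expect_lt(max(abs(op_big$G %*% Y)), 1e-8)

  # underdetermined single-row system: minimum-norm solution
  op_row <- mne_operator(matrix(c(1, 1), 1, 2), 1e-12)
  expect_equal(apply_inverse(op_row, 2), c(1, 1), tolerance = 1e-6)

  # rank-deficient gram at lambda = 0
  expect_error(mne_operator(matrix(c(1, 1, 1, 1), 2, 2), 0), "lambda > 0")
})

test_that("MNE residual shrinks monotonically as lambda decreases", {
  set.seed(9)
  L <- matrix(rnorm(10 * 25), 10, 25)
  s <- rnorm(25)
  Y <- L %*% s # in the range of L
  lams <- 10^seq(2, -6, by = -2)
  res <- vapply(lams, function(l) {
    norm(Y - L %*% (mne_operator(L, l)$G %*% Y), "F")
  }, numeric(1))
  expect_true(all(diff(res) < 1e-10))
  expect_lt(res[length(res)], 1e-6 * norm(Y, "F"))
})

test_that("sLORETA is nonnegative and localizes noiseless dipoles exactly", {
  h <- tiny_head()
  lf <- eeg_leadfield(h$space, fibonacci_sensors(24, 0.10, "eeg"))
  lam <- default_lambda(lf) # avg-ref leadfield needs lambda > 0

  # identity leadfield: standardization is uniform, argmax follows |Y|
  y <- c(0.1, -2, 0.5, 1)
  mI <- sloreta_solve(diag(4), y, 1e-9)
  expect_true(all(mI >= 0))
  expect_equal(which.max(mI), which.max(abs(y)))

  # zero-localization-error property across every source position
  les <- vapply(seq_len(42), function(n) {
    y <- lf$L[, n]
    m <- sloreta_solve(lf, y, lam)
    patch <- list(centers = n)
    localization_error(m, patch, h$D)
  }, numeric(1))
  expect_true(all(les == 0))
})

test_that("dSPM normalizes by the noise-projected standard deviation", {
  set.seed(3)
  L <- matrix(rnorm(8 * 20), 8, 20)
  Y <- rnorm(8)
  lam <- 0.1
  m1 <- dspm_solve(L, Y, lam, diag(8))
  # scaling the noise covariance by c^2 scales the map by 1/c
  m2 <- dspm_solve(L, Y, lam, 4 * diag(8))
  expect_equal(m2, m1 / 2, tolerance = 1e-10)

  # identity system with unit covariance: map equals Y (up to regularization)
  mI <- dspm_solve(diag(5), c(1, -2, 0.5, 3, -1), 1e-10, diag(5))
  expect_equal(mI, c(1, -2, 0.5, 3, -1), tolerance = 1e-6)

  expect_error(dspm_solve(L, Y, lam, -diag(8)), "positive definite")
  # an all-zero leadfield column makes the operator row zero
  L0 <- L; L0[, 3] <- 0
  expect_error(dspm_solve(L0, Y, lam, diag(8)), "zero")
})

test_that("SNR-transformation fusion whitens and stacks the two modalities", {
  set.seed(12)
  Le <- matrix(rnorm(6 * 15), 6, 15)
  Lm <- matrix(rnorm(9 * 15), 9, 15)
  s <- rnorm(15)
  sd_e <- 2; sd_m <- 0.5
  Ye <- Le %*% s; Ym <- Lm %*% s
  fused <- snr_fuse(Ye, Le, sd_e, Ym, Lm, sd_m)
  expect_equal(nrow(fused$Y), 15)
  expect_equal(nrow(fused$L), 15)

  # whitened noise has unit variance: simulate under the stated noise model
  reps <- 4000
  ne <- matrix(rnorm(6 * reps, sd = sd_e), 6, reps)
  nm <- matrix(rnorm(9 * reps, sd = sd_m), 9, reps)
  wn <- rbind(ne / sd_e, nm / sd_m)
  expect_equal(mean(apply(wn, 1, var)), 1, tolerance = 0.1)

  # fusing a modality with itself preserves the MNE argmax
  lam <- 0.05
  self_fused <- snr_fuse(Ye, Le, sd_e, Ye, Le, sd_e)
  a1 <- which.max(abs(apply_inverse(mne_operator(Le, lam), Ye)))
  a2 <- which.max(abs(apply_inverse(mne_operator(self_fused$L, lam), self_fused$Y)))
  expect_equal(a1, a2)

  expect_error(snr_fuse(Ye, Le, 0, Ym, Lm, sd_m), "> 0")
  expect_error(snr_fuse(Ye[-1, , drop = FALSE], Le, 1, Ym, Lm, 1), "disagree")
})

test_that("all solvers are linear in the measurements", {
  set.seed(21)
  L <- matrix(rnorm(10 * 18), 10, 18)
  y1 <- rnorm(10); y2 <- rnorm(10)
  op <- mne_operator(L, 0.2)
  expect_equal(apply_inverse(op, 2 * y1 + y2),
               2 * apply_inverse(op, y1) + apply_inverse(op, y2),
               tolerance = 1e-12)
  # dSPM is linear; sLORETA is quadratic in Y but its underlying standardized
  # amplitude is linear, i.e. the map of c*y is c^2 times the map of y
  expect_equal(sloreta_solve(L, 3 * y1, 0.2), 9 * sloreta_solve(L, y1, 0.2),
               tolerance = 1e-10)
  expect_equal(dspm_solve(L, 2 * y1, 0.2, diag(10)),
               2 * dspm_solve(L, y1, 0.2, diag(10)), tolerance = 1e-10)
})
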