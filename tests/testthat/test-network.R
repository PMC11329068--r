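test_that("channel descriptors are per-map means", {
  u <- list(matrix(2, 3, 3), matrix(0, 3, 3), matrix(c(1, 2, 3, 6), 2, 2))
  expect_equal(channel_descriptors(u), c(2, 0, 3))
  A <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  z <- channel_descriptors(A)
  expect_equal(dim(z), c(3, 2))
  expect_equal(z[2, 1], mean(A[, , 2, 1]), tolerance = 1e-14)
})

test_that("attention weights follow sigmoid(W2 relu(W1 z)) and stay in (0,1)", {
  expect_equal(attention_weights(c(0, 0), diag(2), diag(2)), c(0.5, 0.5))
  expect_equal(attention_weights(c(3, -1), diag(2) * 0, diag(2) * 0), c(0.5, 0.5))
  w <- attention_weights(1, matrix(1), matrix(2))
  expect_equal(w, 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(w, 0.880797, tolerance = 1e-6)
  # negative pre-activation is clipped by the ReLU
  expect_equal(attention_weights(-1, matrix(1), matrix(2)), 0.5)

  set.seed(1)
  z <- rnorm(8)
  W1 <- matrix(rnorm(16), 2, 8); W2 <- matrix(rnorm(16), 8, 2)
  w <- attention_weights(z, W1, W2)
  expect_true(all(w > 0 & w < 1))
  expect_error(attention_weights(z, W1[, -1], W2), "mismatch")

  u <- list(matrix(1, 2, 2), matrix(2, 2, 2))
  expect_equal(apply_attention(u, c(1, 1)), u)
  expect_equal(apply_attention(u, c(0, 0.5))[[2]], matrix(1, 2, 2))
})

test_that("forward pass is deterministic with a linear output head", {
  d <- tiny_descriptor()
  m <- fusion_model(d, seed = 3)
  set.seed(5)
  xe <- matrix(rnorm(64 * 3), 64, 3); xm <- matrix(rnorm(64 * 3), 64, 3)
  out1 <- fusion_forward(m, xe, xm)
  out2 <- fusion_forward(m, xe, xm)
  expect_identical(out1, out2)
  expect_equal(dim(out1), c(42, 3))

  # doubling the output layer doubles the output minus the bias path
  m2 <- m
  m2$params$out_W <- 2 * m$params$out_W
  m2$params$out_b <- 2 * m$params$out_b
  expect_equal(fusion_forward(m2, xe, xm), 2 * out1, tolerance = 1e-12)

  # zero inputs with zero biases leave only the bias path; with zero biases
  # the hidden ReLU sees the attention-gated zero maps, so output is out_b
  m0 <- m
  for (nm in grep("_b$", names(m0$params), value = TRUE)) {
    m0$params[[nm]] <- m0$params[[nm]] * 0
  }
  out0 <- fusion_forward(m0, matrix(0, 64, 1), matrix(0, 64, 1))
  expect_equal(drop(out0), m0$params$out_b, tolerance = 1e-12)

  expect_error(fusion_forward(m, matrix(0, 60, 1), matrix(0, 64, 1)), "grid")
})

test_that("losses match hand-computed values", {
  # MSE: mean over snapshots of squared distance
  expect_equal(mse_loss(c(1, 0, 0), c(0, 0, 0)), 1)
  expect_equal(mse_loss(rbind(c(1, 0), c(1, 2)), matrix(0, 2, 2)), 3) # (2 + 4)/2
  expect_equal(mse_loss(1:5, 1:5), 0)

  # topological loss: point-mass mislocalization
  N <- 6
  D <- matrix(50, N, N); diag(D) <- 0
  D[2, 5] <- D[5, 2] <- 10
  M <- topology_matrix(D, rho = 0.005, tau = 100)
  s <- numeric(N); s[2] <- 1
  sh <- numeric(N); sh[5] <- 1
  expect_equal(topological_loss(s, sh, M), 2 * tanh(0.005 * 10)^2 / N^2,
               tolerance = 1e-12)

  # purely local amplitude error touches only the masked diagonal
  sh2 <- s; sh2[2] <- 0.4
  expect_equal(topological_loss(s, sh2, M), 0)
  expect_equal(topological_loss(s, s, M), 0)

  cfg <- loss_config(M, alpha = 0.05)
  expect_equal(total_loss(s, sh, cfg),
               mse_loss(s, sh) + 0.05 * topological_loss(s, sh, M))
  cfg0 <- loss_config(M, alpha = 0)
  set.seed(8)
  a <- runif(N); b <- runif(N)
  expect_identical(total_loss(a, b, cfg0), mse_loss(a, b))
  expect_error(loss_config(M, alpha = 1.2), "alpha")
})

test_that("topological loss grows with the displacement ring of a point mass", {
  h <- tiny_head()
  M <- topology_matrix(h$D, rho = 0.005, tau = 100)
  hops <- igraph::distances(h$graph, v = 1, weights = NA)[1, ]
  s <- numeric(42); s[1] <- 1
  by_ring <- vapply(1:4, function(k) {
    js <- which(hops == k)
    mean(vapply(js, function(j) {
      sh <- numeric(42); sh[j] <- 1
      topological_loss(s, sh, M)
    }, numeric(1)))
  }, numeric(1))
  # non-decreasing overall; strictly increasing while below the saturation
  # threshold tau (remote rings saturate at m = 1)
  expect_true(all(diff(by_ring) >= -1e-12))
  expect_gt(by_ring[2], by_ring[1])
  expect_true(all(by_ring > 0))
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(13)
  N <- 10
  D <- as.matrix(stats::dist(matrix(rnorm(N * 3), N, 3))) * 40
  M <- topology_matrix(D, rho = 0.01, tau = 80)
  cfg <- loss_config(M, alpha = 0.3)
  s <- abs(rnorm(N)); sh <- rnorm(N)
  g <- total_loss_grad(s, sh, cfg)
  fd <- vapply(seq_len(N), function(i) {
    h <- 1e-6
    shp <- sh; shp[i] <- shp[i] + h
    shm <- sh; shm[i] <- shm[i] - h
    (total_loss(s, shp, cfg) - total_loss(s, shm, cfg)) / (2 * h)
  }, numeric(1))
  expect_equal(drop(g), fd, tolerance = 1e-4)
})

test_that("weight gradients agree with finite differences on smooth inputs", {
  d <- fusion_descriptor(grid = c(8, 8), n_out = 10, conv_filters = c(3, 4),
                         fc_hidden = 6, reduction = 2)
  m <- fusion_model(d, seed = 7)
  set.seed(5)
  B <- 2
  xe <- matrix(rnorm(64 * B), 64, B); xm <- matrix(rnorm(64 * B), 64, B)
  st <- matrix(abs(rnorm(10 * B)), 10, B)
  Dm <- as.matrix(stats::dist(matrix(rnorm(30), 10, 3))) * 50
  cfg <- loss_config(topology_matrix(Dm, 0.005, 100), alpha = 0.05)

  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    cc <- fusion_forward(m2, xe, xm, cache = TRUE)
    fusionesi:::batch_total_loss(st, cc$s_hat, cfg)
  }
  cc <- fusion_forward(m, xe, xm, cache = TRUE)
  e <- st - cc$s_hat
  Q <- (cfg$M^2) %*% e^2
  ds_hat <- -(2 * e + cfg$alpha * 4 * e * Q / 100) / B
  gr <- fusionesi:::fusion_backward(m, cc, ds_hat)

  for (nm in c("eeg_conv1_W", "meg_conv2_W", "eeg_att_W1", "meg_att_W2",
               "fc1_W", "out_W", "meg_conv1_b", "fc1_b")) {
    p <- m$params[[nm]]
    idx <- seq_len(min(length(p), 6))
    for (i in idx) {
      h <- 1e-6 * max(1, abs(p[i]))
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training overfits a single sample and is seed-reproducible", {
  ds <- tiny_set()
  tr <- split_samples(ds, "train")
  M <- topology_matrix(ds$head$D, 0.005, 100)
  cfg <- loss_config(M, alpha = 0.05)
  m <- fusion_model(tiny_descriptor(), seed = 2)

  one <- list(x_eeg = tr$x_eeg[1, , drop = FALSE],
              x_meg = tr$x_meg[1, , drop = FALSE],
              s = tr$s[1, , drop = FALSE])
  fit <- train_fusion_model(m, one, NULL, cfg, epochs = 200, batch_size = 1,
                            lr = 3e-3, seed = 1)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.01 * h$train_loss[1])

  few <- list(x_eeg = tr$x_eeg[1:8, ], x_meg = tr$x_meg[1:8, ], s = tr$s[1:8, ])
  f1 <- train_fusion_model(fusion_model(tiny_descriptor(), seed = 2), few, NULL,
                           cfg, epochs = 5, batch_size = 4, seed = 3)
  f2 <- train_fusion_model(fusion_model(tiny_descriptor(), seed = 2), few, NULL,
                           cfg, epochs = 5, batch_size = 4, seed = 3)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-6)
  expect_equal(f1$model$params$out_W, f2$model$params$out_W, tolerance = 1e-8)

  td <- tidy(f1)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "train_loss", "val_loss"))
  g <- glance(f1)
  expect_equal(g$epochs, 5)
  expect_equal(g$alpha, 0.05)
})
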