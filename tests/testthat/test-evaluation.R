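test_that("localization error reads geodesics from the argmax to the nearest center", {
  h <- tiny_head()
  N <- 42
  patch <- grow_patch(h$space, 10, 1, graph = h$graph)

  s <- numeric(N); s[10] <- 1
  expect_equal(localization_error(s, patch, h$D), 0)

  nb <- patch$members$region[patch$members$ring == 1][1]
  s2 <- numeric(N); s2[nb] <- 1
  expect_equal(localization_error(s2, patch, h$D), h$D[nb, 10])
  # one-hop neighbor distance equals that edge length
  expect_equal(h$D[nb, 10],
               igraph::distances(h$graph, v = nb, to = 10,
                                 weights = igraph::E(h$graph)$weight)[1, 1])

  # ties break to the lowest index; sign is ignored
  s3 <- numeric(N); s3[5] <- -0.7; s3[9] <- 0.7
  expect_equal(localization_error(s3, patch, h$D), h$D[5, 10])

  # multi-center: min over centers
  mp <- list(centers = c(3, 30))
  s4 <- numeric(N); s4[31] <- 1
  expect_equal(localization_error(s4, mp, h$D), min(h$D[31, c(3, 30)]))

  expect_warning(le0 <- localization_error(numeric(N), patch, h$D), "all-zero")
  expect_equal(as.numeric(le0), h$D[1, 10])
  expect_error(localization_error(numeric(10), patch, h$D), "length")
})

test_that("AUPRC implements tie-aware average precision", {
  patch <- list(members = tibble::tibble(region = c(1, 2)))
  # hand example: labels (1,1,0,0), scores (0.9, 0.4, 0.6, 0.1)
  expect_equal(auprc(c(0.9, 0.4, 0.6, 0.1), patch), (1 + 2 / 3) / 2)
  # perfect ranking
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), patch), 1.0)
  # all-tied scores collapse to prevalence
  expect_equal(auprc(rep(0.5, 4), patch), 0.5)
  patch1 <- list(members = tibble::tibble(region = 3))
  expect_equal(auprc(rep(1, 10), patch1), 0.1)

  expect_error(auprc(rep(1, 4), list(members = tibble::tibble(region = 1:4))),
               "degenerate")
  expect_error(auprc(rep(1, 4), list(members = tibble::tibble(region = integer()))),
               "degenerate")
})

test_that("AUPRC agrees with an independent threshold-scan oracle", {
  set.seed(17)
  for (rep in seq_len(300)) {
    n <- sample(5:40, 1)
    npos <- sample(seq_len(n - 1), 1)
    labels <- logical(n); labels[sample(n, npos)] <- TRUE
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # force ties sometimes
    patch <- list(members = tibble::tibble(region = which(labels)))
    expect_equal(auprc(scores, patch), ap_oracle(labels, scores),
                 tolerance = 1e-9)
  }
})

test_that("localization error agrees with a brute-force center scan", {
  h <- tiny_head()
  set.seed(23)
  for (rep in seq_len(50)) {
    centers <- sample(42, sample(1:3, 1))
    s_hat <- rnorm(42)
    le <- localization_error(s_hat, list(centers = centers), h$D)
    amax <- which(abs(s_hat) == max(abs(s_hat)))[1]
    expect_equal(le, min(vapply(centers, function(ctr) h$D[amax, ctr], numeric(1))))
  }
})

test_that("experiment runner produces per-sample records for each method", {
  ds <- tiny_set()
  rec <- run_experiment(ds, methods = c("mne", "sloreta"))
  n_test <- sum(ds$meta$split == "test")
  expect_equal(nrow(rec), 2 * n_test)
  expect_setequal(unique(rec$method), c("mne", "sloreta"))
  expect_true(all(rec$le_mm >= 0))
  expect_true(all(rec$auprc >= 0 & rec$auprc <= 1))

  expect_error(run_experiment(ds, methods = "fused"), "no `fit`")

  sm <- summarize_experiment(rec)
  expect_equal(nrow(sm), 2)
  expect_true(all(sm$n == n_test))
  # constant records have zero spread
  cons <- rec
  cons$le_mm <- 1; cons$auprc <- 0.5
  sm2 <- summarize_experiment(cons)
  expect_equal(sm2$le_sd, c(0, 0))

  # determinism: same call, same records
  rec2 <- run_experiment(ds, methods = c("mne", "sloreta"))
  expect_equal(rec, rec2)
})

test_that("baselines comfortably beat random guessing on clean data", {
  ds <- tiny_set()
  rec <- run_experiment(ds, methods = "sloreta")
  expect_lt(mean(rec$le_mm), 0.5 * random_guess_le(ds$head$D))
  expect_gt(mean(rec$auprc), 0.5)
})

test_that("the ablation grid is the nine-cell modality/dilation/loss design", {
  cells <- ablation_cells()
  expect_equal(nrow(cells), 9)
  expect_equal(sum(cells$eeg & cells$meg), 3)
  expect_equal(sum(cells$dilation == 2), 6)
  expect_equal(cells$model[cells$topo], c("M7", "M8", "M9"))
  # the fusion-vs-single comparisons exist at matched dilation/loss settings
  expect_true(all(c("M1", "M2", "M3") %in% cells$model[cells$dilation == 1]))
})

test_that("a small ablation subset trains per cell and yields paired records", {
  ds <- tiny_set()
  cells <- ablation_cells()[c(4, 6), ] # EEG-only and fused, dilation 2
  res <- run_ablation(ds, cells = cells, epochs = 3, batch_size = 8, seed = 5,
                      descriptor_args = list(conv_filters = c(4, 8),
                                             fc_hidden = 24))
  n_test <- sum(ds$meta$split == "test")
  expect_equal(nrow(res$records), 2 * n_test)
  expect_setequal(unique(res$records$model), c("M4", "M6"))
  expect_equal(nrow(res$summary), 2)
  # paired: same samples in both cells
  expect_equal(sort(res$records$sample[res$records$model == "M4"]),
               sort(res$records$sample[res$records$model == "M6"]))

  res2 <- run_ablation(ds, cells = cells[1, ], epochs = 3, batch_size = 8,
                       seed = 5,
                       descriptor_args = list(conv_filters = c(4, 8),
                                              fc_hidden = 24))
  expect_equal(res2$records$le_mm,
               res$records$le_mm[res$records$model == "M4"], tolerance = 1e-8)
})

test_that("hyperparameter search evaluates the default first and tracks the best", {
  ds <- tiny_set()
  res <- tune_hyperparameters(ds, budget = 2, epochs = 2, batch_size = 8,
                              seed = 3,
                              descriptor_args = list(conv_filters = c(4, 8),
                                                     fc_hidden = 24))
  expect_equal(nrow(res$history), 2)
  expect_equal(res$history$alpha[1], 0.05)
  expect_equal(res$history$rho[1], 0.005)
  expect_gte(res$best_objective, res$history$objective[1])
  expect_true(res$best_alpha >= 0.001 && res$best_alpha <= 1)

  b1 <- tune_hyperparameters(ds, budget = 1, epochs = 2, batch_size = 8,
                             seed = 3,
                             descriptor_args = list(conv_filters = c(4, 8),
                                                    fc_hidden = 24))
  expect_equal(nrow(b1$history), 1)
  expect_equal(b1$best_trial, 1)
  expect_error(tune_hyperparameters(ds, budget = 0), "budget")
  expect_error(search_space(alpha_range = c(0.5, 0.1)), "low < high")
})
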