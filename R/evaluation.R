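#' Localization error
#'
#' Geodesic mesh distance (mm) between the region carrying the maximum
#' reconstructed amplitude and the nearest true patch center. Amplitudes are
#' compared by absolute value; ties break to the lowest region index. An
#' all-zero estimate returns the distance from region 1 and carries a
#' `degenerate` attribute.
#'
#' @param s_hat Length-N estimated source vector.
#' @param patch A `source_patch` (its `centers` are used).
#' @param D Geodesic distance matrix (mm) from [geodesic_all_pairs()].
#' @return Localization error in mm.
#' @export
localization_error <- function(s_hat, patch, D) {
  if (length(s_hat) != nrow(D)) stop("`s_hat` length does not match `D`")
  if (length(patch$centers) < 1) stop("patch has no centers")
  a <- abs(s_hat)
  degenerate <- all(a == 0)
  if (degenerate) {
    warning("all-zero estimate; localization error measured from region 1")
  }
  amax <- which.max(a) # first (= lowest-index) maximum
  le <- min(D[amax, patch$centers])
  if (degenerate) attr(le, "degenerate") <- TRUE
  le
}

#' Area under the precision-recall curve
#'
#' Binary labels are patch membership; scores are absolute reconstructed
#' amplitudes. The area is computed by the step-wise average-precision rule
#' (sum of precision times recall increments at each distinct score), the
#' convention appropriate for the heavily imbalanced active/inactive split.
#'
#' @param s_hat Length-N estimated source vector.
#' @param patch A `source_patch`; must be non-empty and not cover all N
#'   regions.
#' @return Average precision in [0, 1].
#' @export
auprc <- function(s_hat, patch) {
  n <- length(s_hat)
  labels <- logical(n)
  labels[patch$members$region] <- TRUE
  np <- sum(labels)
  if (np == 0 || np == n) stop("degenerate label set: patch empty or covers all regions")
  average_precision(labels, abs(s_hat))
}

# tie-aware step-wise average precision
average_precision <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  # block boundaries at distinct score values
  ends <- c(which(diff(sc) != 0), length(sc))
  tp <- cumsum(lab)[ends]
  fp <- cumsum(!lab)[ends]
  npos <- sum(labels)
  rec <- tp / npos
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Random-guess localization-error level
#'
#' Mean geodesic distance from a uniformly random region to a uniformly
#' random target — the chance floor that any useful method must beat.
#'
#' @param D Geodesic distance matrix (mm).
#' @return Mean off-diagonal distance in mm.
#' @export
random_guess_le <- function(D) {
  n <- nrow(D)
  sum(D) / (n * (n - 1))
}

#' Evaluate methods on a test sample set
#'
#' Computes per-sample localization error and AUPRC for any mix of the
#' trained fusion model and the classical baselines. Baselines solve the
#' SNR-whitened stacked EEG+MEG system ([snr_fuse()]); per-modality noise
#' SDs are derived from each sample's known target SNR, and dSPM uses the
#' identity noise covariance of the whitened system.
#'
#' @param set A `sample_set`.
#' @param methods Character vector from `c("fused", "mne", "sloreta",
#'   "dspm")`.
#' @param fit A `fusion_fit` (required when `"fused"` is requested).
#' @param split Which split to evaluate (default `"test"`).
#' @param lambda Regularization for the baselines; default
#'   [default_lambda()] of the whitened system at the sample's SNR.
#' @return An `esi_records` tibble: `method`, `sample`, `lns`, `snr_db`,
#'   `ns`, `le_mm`, `auprc`.
#' @export
run_experiment <- function(set, methods = c("fused", "mne", "sloreta", "dspm"),
                           fit = NULL, split = "test", lambda = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("fused" %in% methods && is.null(fit)) {
    stop("method 'fused' requested but no `fit` supplied")
  }
  te <- split_samples(set, split)
  n_te <- nrow(te$s)
  if (n_te == 0) stop(sprintf("no samples in split '%s'", split))
  head <- set$head
  N <- ncol(set$s)

  pred_fused <- NULL
  if ("fused" %in% methods) {
    pred_fused <- predict(fit, te$x_eeg, te$x_meg)
    pred_fused <- matrix(pred_fused, n_te, N)
  }

  rows <- vector("list", length(methods) * n_te)
  k <- 0L
  for (i in seq_len(n_te)) {
    patch <- te$patches[[i]]
    snr <- te$meta$snr_db[i]
    base_est <- NULL
    if (any(methods != "fused")) {
      sd_e <- noise_sd_from_snr(te$y_eeg[i, ], snr)
      sd_m <- noise_sd_from_snr(te$y_meg[i, ], snr)
      fused_sys <- snr_fuse(te$y_eeg[i, ], head$lf_eeg, sd_e,
                            te$y_meg[i, ], head$lf_meg, sd_m)
      lam <- lambda %||% default_lambda(fused_sys$L, snr)
      base_est <- list()
      if ("mne" %in% methods) {
        base_est$mne <- apply_inverse(mne_operator(fused_sys$L, lam), fused_sys$Y)
      }
      if ("sloreta" %in% methods) {
        base_est$sloreta <- sloreta_solve(fused_sys$L, fused_sys$Y, lam)
      }
      if ("dspm" %in% methods) {
        base_est$dspm <- dspm_solve(fused_sys$L, fused_sys$Y, lam,
                                    diag(nrow(fused_sys$Y)))
      }
    }
    for (m in methods) {
      est <- if (m == "fused") pred_fused[i, ] else base_est[[m]]
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        method = m, sample = te$meta$sample[i], lns = te$meta$lns[i],
        snr_db = snr, ns = te$meta$ns[i],
        le_mm = as.numeric(localization_error(est, patch, head$D)),
        auprc = auprc(est, patch)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("esi_records", class(out))
  out
}

# noise SD consistent with a noisy measurement at a known target SNR:
# P_noisy = P_sig (1 + 1/snr), noise variance = P_sig / snr
noise_sd_from_snr <- function(y, snr_db) {
  snr <- 10^(snr_db / 10)
  p_sig <- mean(y^2) / (1 + 1 / snr)
  sqrt(p_sig / snr)
}

#' Summarize evaluation records as mean +/- sd per condition
#'
#' @param records An `esi_records` tibble from [run_experiment()] or
#'   [run_ablation()].
#' @param ... Grouping columns (defaults to `method`).
#' @return Tibble of group means and standard deviations of `le_mm` and
#'   `auprc`, with `n` samples per cell.
#' @export
summarize_experiment <- function(records, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) groups <- rlang::quos(method)
  records |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n = dplyr::n(),
      le_mean = mean(.data$le_mm), le_sd = stats::sd(.data$le_mm),
      auprc_mean = mean(.data$auprc), auprc_sd = stats::sd(.data$auprc),
      .groups = "drop"
    )
}

#' Ablation grid over modality, dilation and topological loss
#'
#' The default grid is the nine-cell design M1-M9: modality in
#' {EEG, MEG, EEG+MEG} crossed with dilation 1 vs 2 (without the topological
#' term), plus the three dilation-2 cells with the topological term enabled.
#' Single-modality cells feed that modality's encoding to both branches so
#' the architecture is identical across cells. All cells share the dataset,
#' the initialization seed and the training schedule, giving paired
#' per-sample records.
#'
#' @param set A `sample_set`.
#' @param cells Optional tibble with columns `model`, `eeg`, `meg`,
#'   `dilation`, `topo` to run a subset of the grid.
#' @param alpha,rho,tau Loss hyperparameters for topo-enabled cells.
#' @param epochs,batch_size,lr,patience,seed Training controls (shared by
#'   every cell).
#' @param descriptor_args Extra arguments to [fusion_descriptor()].
#' @param verbose Print progress?
#' @return List with `records` (`esi_records` with a `model` column),
#'   `summary`, `cells`, and `fits` (named list of `fusion_fit`s).
#' @export
run_ablation <- function(set, cells = NULL, alpha = 0.05, rho = 0.005,
                         tau = 100, epochs = 20, batch_size = 64, lr = 1e-3,
                         patience = 20, seed = 1L, descriptor_args = list(),
                         verbose = FALSE) {
  if (is.null(cells)) cells <- ablation_cells()
  head <- set$head
  N <- ncol(set$s)
  tr <- split_samples(set, "train")
  va <- split_samples(set, "val")
  if (nrow(va$s) == 0) va <- NULL

  fits <- list()
  recs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    if (verbose) message("ablation cell ", cell$model)
    d <- do.call(fusion_descriptor, c(
      list(grid = set$config$grid_size, n_out = N, dilation = cell$dilation),
      descriptor_args
    ))
    model <- fusion_model(d, seed = seed)
    cfg <- if (cell$topo) {
      loss_config(topology_matrix(head$D, rho = rho, tau = tau), alpha = alpha)
    } else {
      loss_config(topology_matrix(head$D, rho = rho, tau = tau), alpha = 0)
    }
    pick <- function(sp) cell_inputs(sp, cell)
    fit <- train_fusion_model(model, pick(tr), if (is.null(va)) NULL else pick(va),
                              cfg, epochs = epochs, batch_size = batch_size,
                              lr = lr, patience = patience, seed = seed)
    fits[[cell$model]] <- fit

    te <- split_samples(set, "test")
    tei <- cell_inputs(te, cell)
    pred <- matrix(predict(fit, tei$x_eeg, tei$x_meg), nrow(te$s), N)
    recs[[i]] <- dplyr::bind_rows(lapply(seq_len(nrow(te$s)), function(j) {
      tibble::tibble(
        model = cell$model, sample = te$meta$sample[j], lns = te$meta$lns[j],
        snr_db = te$meta$snr_db[j], ns = te$meta$ns[j],
        le_mm = as.numeric(localization_error(pred[j, ], te$patches[[j]], head$D)),
        auprc = auprc(pred[j, ], te$patches[[j]])
      )
    }))
  }
  records <- dplyr::bind_rows(recs)
  class(records) <- c("esi_records", class(records))
  list(records = records,
       summary = summarize_experiment(records, .data$model),
       cells = cells, fits = fits)
}

# route encodings to branches for an ablation cell
cell_inputs <- function(sp, cell) {
  if (cell$eeg && cell$meg) {
    list(x_eeg = sp$x_eeg, x_meg = sp$x_meg, s = sp$s)
  } else if (cell$eeg) {
    list(x_eeg = sp$x_eeg, x_meg = sp$x_eeg, s = sp$s)
  } else {
    list(x_eeg = sp$x_meg, x_meg = sp$x_meg, s = sp$s)
  }
}

#' The nine-cell ablation design
#'
#' @return Tibble with columns `model`, `eeg`, `meg`, `dilation`, `topo`.
#' @export
ablation_cells <- function() {
  tibble::tibble(
    model = paste0("M", 1:9),
    eeg = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    meg = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    dilation = c(1, 1, 1, 2, 2, 2, 2, 2, 2),
    topo = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Hyperparameter search space
#'
#' @param alpha_range,rho_range Lower/upper bounds (positive, low < high).
#' @return A `search_space` list.
#' @export
search_space <- function(alpha_range = c(0.001, 1), rho_range = c(0.001, 1)) {
  chk <- function(r, nm) {
    if (length(r) != 2 || any(r <= 0) || r[1] >= r[2]) {
      stop(sprintf("`%s` must be positive with low < high", nm))
    }
  }
  chk(alpha_range, "alpha_range"); chk(rho_range, "rho_range")
  structure(list(alpha_range = alpha_range, rho_range = rho_range),
            class = "search_space")
}

#' Tune the loss hyperparameters against validation AUPRC
#'
#' Sequential search over (alpha, rho): trial 1 evaluates the package
#' defaults (alpha = 0.05, rho = 0.005, clipped into the space), subsequent
#' trials draw log-uniformly from the space. Each trial trains a fresh model
#' on the training split and scores the mean AUPRC on the validation split.
#'
#' @param set A `sample_set` with non-empty train and val splits.
#' @param space A [search_space()].
#' @param budget Number of trials (>= 1).
#' @param tau Neighborhood threshold passed to [topology_matrix()].
#' @param epochs,batch_size,lr,seed Training controls per trial.
#' @param descriptor_args Extra arguments to [fusion_descriptor()].
#' @param verbose Print per-trial objectives?
#' @return A `tune_result`: list with `best_alpha`, `best_rho`,
#'   `best_objective`, `best_trial` and a `history` tibble (`trial`, `alpha`,
#'   `rho`, `objective`).
#' @export
tune_hyperparameters <- function(set, space = search_space(), budget = 10,
                                 tau = 100, epochs = 10, batch_size = 64,
                                 lr = 1e-3, seed = 1L, descriptor_args = list(),
                                 verbose = FALSE) {
  if (budget < 1) stop("`budget` must be >= 1")
  head <- set$head
  N <- ncol(set$s)
  tr <- split_samples(set, "train")
  va <- split_samples(set, "val")
  if (nrow(va$s) == 0) stop("tuning needs a validation split")

  clip <- function(x, r) min(max(x, r[1]), r[2])
  pts <- withr_seed(seed + 31L, {
    loguni <- function(r, m) exp(stats::runif(m, log(r[1]), log(r[2])))
    tibble::tibble(
      alpha = c(clip(0.05, space$alpha_range), loguni(space$alpha_range, budget - 1)),
      rho = c(clip(0.005, space$rho_range), loguni(space$rho_range, budget - 1))
    )
  })

  obj <- numeric(budget)
  for (t in seq_len(budget)) {
    d <- do.call(fusion_descriptor,
                 c(list(grid = set$config$grid_size, n_out = N), descriptor_args))
    model <- fusion_model(d, seed = seed)
    cfg <- loss_config(topology_matrix(head$D, rho = pts$rho[t], tau = tau),
                       alpha = pts$alpha[t])
    fit <- train_fusion_model(model, tr, val = NULL, cfg, epochs = epochs,
                              batch_size = batch_size, lr = lr, seed = seed)
    pred <- matrix(predict(fit, va$x_eeg, va$x_meg), nrow(va$s), N)
    obj[t] <- mean(vapply(seq_len(nrow(va$s)), function(j) {
      auprc(pred[j, ], va$patches[[j]])
    }, numeric(1)))
    if (verbose) {
      message(sprintf("trial %2d alpha=%.4g rho=%.4g objective=%.4f",
                      t, pts$alpha[t], pts$rho[t], obj[t]))
    }
  }
  best <- which.max(obj)
  structure(
    list(best_alpha = pts$alpha[best], best_rho = pts$rho[best],
         best_objective = obj[best], best_trial = best,
         history = tibble::tibble(trial = seq_len(budget), alpha = pts$alpha,
                                  rho = pts$rho, objective = obj)),
    class = "tune_result"
  )
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf(
    "<tune_result> %d trials; best objective %.4f at trial %d (alpha=%.4g, rho=%.4g)\n",
    nrow(x$history), x$best_objective, x$best_trial, x$best_alpha, x$best_rho
  ))
  invisible(x)
}
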