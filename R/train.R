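#' Loss functions
#'
#' The training objective combines a mean-squared-error term with a
#' *topological* term that weights the outer product of the error vector by a
#' geodesic-distance mask, so that mislocalizations far from the truth cost
#' more than equally large errors nearby:
#' \deqn{L = L_{mse} + \alpha L_t,\qquad
#'   L_{mse} = \frac{1}{K}\sum_{i=1}^K \|s_i - s_i'\|_2^2,\qquad
#'   L_t = \frac{1}{N^2}\sum_{i=1}^K \|E_i \odot M\|_F^2,\ E_i = (s_i - s_i')(s_i - s_i')^T.}
#' Note the topological term sums over the K snapshots as written, without an
#' extra 1/K average; with the single-snapshot samples used here the two
#' conventions coincide.
#'
#' @param s Ground-truth source amplitudes: N x K matrix (or length-N vector).
#' @param s_hat Estimate, same shape.
#' @param M Topological weight matrix from [topology_matrix()].
#' @param cfg A [loss_config()].
#' @name losses
NULL

#' @rdname losses
#' @export
mse_loss <- function(s, s_hat) {
  s <- as_snapshot_matrix(s); s_hat <- as_snapshot_matrix(s_hat)
  if (!all(dim(s) == dim(s_hat))) stop("`s` and `s_hat` must have equal shapes")
  mean(colSums((s - s_hat)^2))
}

#' @rdname losses
#' @export
topological_loss <- function(s, s_hat, M) {
  s <- as_snapshot_matrix(s); s_hat <- as_snapshot_matrix(s_hat)
  if (!all(dim(s) == dim(s_hat))) stop("`s` and `s_hat` must have equal shapes")
  N <- nrow(s)
  if (!all(dim(M) == c(N, N))) stop("`M` dimension does not match the source space")
  E2 <- (s - s_hat)^2                       # N x K, columns e_i^2
  M2 <- unclass(M)^2
  sum(colSums(E2 * (M2 %*% E2))) / (N * N)  # sum_k e2' M2 e2
}

#' Loss configuration
#'
#' @param M Topological weight matrix ([topology_matrix()]).
#' @param alpha Weight of the topological term, in [0, 1]. Default 0.05.
#' @return A `loss_config` list with `alpha`, `M` and the `rho`/`tau` the
#'   matrix was built with.
#' @export
loss_config <- function(M, alpha = 0.05) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  structure(
    list(alpha = alpha, M = unclass(M),
         rho = attr(M, "rho"), tau = attr(M, "tau")),
    class = "loss_config"
  )
}

#' @rdname losses
#' @export
total_loss <- function(s, s_hat, cfg) {
  l <- mse_loss(s, s_hat)
  if (cfg$alpha > 0) l <- l + cfg$alpha * topological_loss(s, s_hat, cfg$M)
  l
}

#' Gradient of the total loss with respect to the estimate
#'
#' Analytic gradient used by the training loop (and checkable against finite
#' differences): with e = s - s_hat,
#' d/ds_hat = 2e/K for the MSE term and 4 alpha e (M^2 e^2) / N^2 for the
#' topological term (per snapshot).
#'
#' @inheritParams losses
#' @return Matrix of the same shape as `s_hat`.
#' @export
total_loss_grad <- function(s, s_hat, cfg) {
  s <- as_snapshot_matrix(s); s_hat <- as_snapshot_matrix(s_hat)
  e <- s - s_hat
  K <- ncol(s); N <- nrow(s)
  g <- 2 * e / K
  if (cfg$alpha > 0) {
    M2 <- cfg$M^2
    g <- g + cfg$alpha * 4 * e * (M2 %*% e^2) / (N * N)
  }
  -g # derivative w.r.t. s_hat (e decreases as s_hat grows)
}

as_snapshot_matrix <- function(s) {
  if (is.null(dim(s))) matrix(s, ncol = 1) else as.matrix(s)
}

# ---- training ---------------------------------------------------------------

#' Train the fusion model
#'
#' Minimizes the combined loss with Adam over shuffled mini-batches. The
#' per-batch objective is the mean over batch samples of the per-sample total
#' loss. Deterministic given `seed` (weight init is the model's; batching and
#' nothing else consumes randomness here). Training aborts with a diagnostic
#' if the loss becomes non-finite.
#'
#' @param model A [fusion_model()].
#' @param train List with `x_eeg`, `x_meg` (samples x grid cells) and `s`
#'   (samples x N), e.g. from [split_samples()].
#' @param val Optional validation list of the same form; enables early
#'   stopping.
#' @param loss_cfg A [loss_config()].
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Mini-batch size (default 64; per-step cost is dominated by parameter traffic, so larger batches cut wall-clock roughly in half versus 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Early-stopping patience in epochs (default 20); the
#'   returned model carries the best validation-loss parameters.
#' @param seed Seed for batch shuffling.
#' @param verbose Print per-epoch losses?
#' @return A `fusion_fit`: list with `model` (trained), `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`), `best_epoch`, `loss_cfg`.
#' @export
train_fusion_model <- function(model, train, val = NULL, loss_cfg,
                               epochs = 50, batch_size = 64, lr = 1e-3,
                               patience = 20, seed = 1L, verbose = FALSE) {
  n <- nrow(train$s)
  if (n < 1) stop("empty training set")
  d <- model$descriptor
  params <- lapply(model$params, function(p) p + 0) # private copy; Adam mutates in place
  opt <- adam_init(params)
  M2 <- if (loss_cfg$alpha > 0) loss_cfg$M^2 else NULL
  N <- d$n_out

  best_val <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", epochs)

  for (ep in seq_len(epochs)) {
    ord <- withr_seed(seed + ep, sample.int(n))
    ep_loss <- 0; ep_n <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      B <- length(idx)
      xe <- t(train$x_eeg[idx, , drop = FALSE]) # (G) x B
      xm <- t(train$x_meg[idx, , drop = FALSE])
      s_true <- t(train$s[idx, , drop = FALSE]) # N x B

      model$params <- params
      cc <- fusion_forward(model, xe, xm, cache = TRUE)
      e <- s_true - cc$s_hat
      l_mse <- colSums(e^2)
      if (!is.null(M2)) {
        E2 <- e^2
        Q <- M2 %*% E2
        l_t <- colSums(E2 * Q) / (N * N)
        batch_loss <- mean(l_mse + loss_cfg$alpha * l_t)
        ds_hat <- -(2 * e + loss_cfg$alpha * 4 * e * Q / (N * N)) / B
      } else {
        batch_loss <- mean(l_mse)
        ds_hat <- -2 * e / B
      }
      if (!is.finite(batch_loss)) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (try a smaller lr)", ep
        ))
      }
      grads <- fusion_backward(model, cc, ds_hat)
      step <- adam_step(opt, params, grads, lr)
      params <- step$params; opt <- step$opt
      ep_loss <- ep_loss + batch_loss * B; ep_n <- ep_n + B
    }
    train_loss <- ep_loss / ep_n

    val_loss <- NA_real_
    if (!is.null(val) && nrow(val$s) > 0) {
      model$params <- params
      sv <- fusion_forward(model, t(val$x_eeg), t(val$x_meg))
      val_loss <- batch_total_loss(t(val$s), as_snapshot_matrix(sv), loss_cfg)
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss
        best_params <- lapply(params, function(p) p + 0) # snapshot
        best_epoch <- ep; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = train_loss,
                                 val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5g  val %.5g", ep, train_loss, val_loss))
    }
    if (!is.null(val) && wait >= patience) break
  }

  if (is.null(val)) { best_params <- params; best_epoch <- ep }
  model$params <- best_params
  structure(
    list(model = model, history = dplyr::bind_rows(hist),
         best_epoch = best_epoch, loss_cfg = loss_cfg),
    class = "fusion_fit"
  )
}

# mean per-sample total loss over a batch (columns = samples)
batch_total_loss <- function(s, s_hat, cfg) {
  e <- s - s_hat
  l <- colSums(e^2)
  if (cfg$alpha > 0) {
    N <- nrow(s)
    E2 <- e^2
    l <- l + cfg$alpha * colSums(E2 * ((cfg$M^2) %*% E2)) / (N * N)
  }
  mean(l)
}

# full backward pass; ds_hat: N x B gradient of the batch loss
fusion_backward <- function(model, cc, ds_hat) {
  p <- model$params
  d <- model$descriptor
  g <- list()

  g$out_W <- tcrossprod(ds_hat, cc$h_fc)
  g$out_b <- rowSums(ds_hat)
  dh <- crossprod(p$out_W, ds_hat)
  da <- dh * (cc$a_fc > 0)
  g$fc1_W <- tcrossprod(da, cc$f)
  g$fc1_b <- rowSums(da)
  df <- crossprod(p$fc1_W, da)

  feat <- nrow(cc$eeg$f)
  g <- c(g, branch_backward(df[seq_len(feat), , drop = FALSE], cc$eeg, p,
                            model$plans, "eeg", d))
  g <- c(g, branch_backward(df[feat + seq_len(feat), , drop = FALSE], cc$meg, p,
                            model$plans, "meg", d))
  g
}

branch_backward <- function(df, cache, p, plans, prefix, d) {
  g <- list()
  U <- cache$U
  dm <- dim(U)
  HW <- dm[1] * dm[2]; C <- dm[3]; B <- dm[4]
  dV <- df
  dim(dV) <- dm

  w <- cache$w # C x B
  Um <- matrix(U, HW, C * B)
  dVm <- matrix(dV, HW, C * B)
  dU <- dVm * rep(as.vector(w), each = HW)
  dw <- matrix(colSums(dVm * Um), C, B)

  da2 <- dw * w * (1 - w)
  W2 <- p[[paste0(prefix, "_att_W2")]]
  W1 <- p[[paste0(prefix, "_att_W1")]]
  g[[paste0(prefix, "_att_W2")]] <- tcrossprod(da2, cache$h)
  dh <- crossprod(W2, da2)
  da1 <- dh * (cache$a1 > 0)
  g[[paste0(prefix, "_att_W1")]] <- tcrossprod(da1, cache$z)
  dz <- crossprod(W1, da1) # C x B
  dU <- dU + rep(as.vector(dz), each = HW) / HW
  dim(dU) <- dm

  nl <- length(d$conv_filters)
  dA <- dU
  for (li in rev(seq_len(nl))) {
    dpre <- dA * (cache[[paste0("pre", li)]] > 0)
    Cin <- if (li == 1) 1L else d$conv_filters[li - 1]
    bk <- conv_backward(dpre, cache[[paste0("cols", li)]],
                        p[[paste0(prefix, "_conv", li, "_W")]],
                        plans[[li]], Cin, B)
    g[[paste0(prefix, "_conv", li, "_W")]] <- bk$dW
    g[[paste0(prefix, "_conv", li, "_b")]] <- bk$db
    dA <- bk$dX
  }
  g
}

# ---- Adam -------------------------------------------------------------------
# The moment buffers and the working parameter copy are owned exclusively by
# the training loop, so the compiled kernel updates them in place.

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
}

adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  adam_update_(params, opt$m, opt$v, grads, lr, opt$beta1, opt$beta2,
               opt$eps, opt$t)
  list(opt = opt, params = params)
}

# ---- fitted-model methods ---------------------------------------------------

#' @export
print.fusion_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<fusion_fit> %d epochs, final train loss %.5g", nrow(h),
              h$train_loss[nrow(h)]))
  if (any(!is.na(h$val_loss))) {
    cat(sprintf(", best val loss %.5g @ epoch %d",
                min(h$val_loss, na.rm = TRUE), x$best_epoch))
  }
  cat("\n")
  invisible(x)
}

#' Predict source amplitudes for new measurements
#'
#' @param object A `fusion_fit`.
#' @param x_eeg,x_meg Encoded inputs: samples x grid-cells matrices (rows are
#'   samples) or single `input_matrix` objects.
#' @param ... Unused.
#' @return samples x N matrix of estimated amplitudes (vector for one sample).
#' @export
predict.fusion_fit <- function(object, x_eeg, x_meg, ...) {
  to_cols <- function(x) {
    if (inherits(x, "input_matrix")) return(matrix(as.vector(x$values), ncol = 1))
    if (is.matrix(x)) t(x) else matrix(x, ncol = 1)
  }
  out <- fusion_forward(object$model, to_cols(x_eeg), to_cols(x_meg))
  if (is.null(dim(out))) out else t(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted fusion model
#'
#' @param x A `fusion_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.fusion_fit <- function(x, ...) x$history

#' One-row summary of a fitted fusion model
#'
#' @param x A `fusion_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `final_train_loss`, `best_val_loss`,
#'   `best_epoch`, `alpha`, `rho`, `n_params`.
#' @export
glance.fusion_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    final_train_loss = h$train_loss[nrow(h)],
    best_val_loss = if (any(!is.na(h$val_loss))) min(h$val_loss, na.rm = TRUE) else NA_real_,
    best_epoch = x$best_epoch,
    alpha = x$loss_cfg$alpha,
    rho = x$loss_cfg$rho %||% NA_real_,
    n_params = sum(vapply(x$model$params, length, numeric(1)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
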