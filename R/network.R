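#' Dual-branch attention fusion network
#'
#' The model maps a pair of topographic input matrices (EEG, MEG) to a vector
#' of source amplitudes. Per branch: a stack of dilated 2-D convolutions with
#' ReLU, then channel attention (global-average descriptors through a
#' squeeze-excite bottleneck, sigmoid gates), then flattening. The two branch
#' features are concatenated and mapped to the N source regions by a fully
#' connected module (ReLU hidden layer, linear output). Both branches share
#' the same hyperparameters but have their own parameters.
#'
#' Internally all activations are stored as 4-D arrays `[H, W, channels,
#' batch]`; convolutions are evaluated as im2col matrix products so the heavy
#' lifting is done by BLAS.
#'
#' @name fusion_network
NULL

#' Architecture descriptor
#'
#' @param grid `c(rows, cols)` of the input matrices.
#' @param n_out Number of source regions (output length).
#' @param conv_filters Filter counts of the per-branch conv stack.
#' @param kernel Square kernel size.
#' @param dilation Dilation rate (>= 1; 1 is a regular convolution).
#' @param reduction Attention bottleneck reduction ratio r (must divide the
#'   last conv filter count).
#' @param fc_hidden Width of the fusion hidden layer.
#' @return A `fusion_descriptor` list.
#' @export
fusion_descriptor <- function(grid = c(16, 16), n_out,
                              conv_filters = c(16, 32), kernel = 3,
                              dilation = 2, reduction = 4, fc_hidden = 512) {
  if (dilation < 1) stop("`dilation` must be >= 1")
  c_last <- conv_filters[length(conv_filters)]
  if (c_last %% reduction != 0) stop("`reduction` must divide the last filter count")
  structure(
    list(grid = grid, n_out = n_out, conv_filters = conv_filters,
         kernel = kernel, dilation = dilation, reduction = reduction,
         fc_hidden = fc_hidden),
    class = "fusion_descriptor"
  )
}

#' Initialize a fusion model
#'
#' He initialization for conv/FC weights, Glorot for the attention
#' bottleneck; zero biases. Deterministic given `seed`.
#'
#' @param descriptor A [fusion_descriptor()].
#' @param seed Integer seed.
#' @return A `fusion_model`: list with `descriptor`, `params` (named list of
#'   matrices/vectors) and conv plans.
#' @export
fusion_model <- function(descriptor, seed = 1L) {
  d <- descriptor
  H <- d$grid[1]; W <- d$grid[2]
  plans <- lapply(seq_along(d$conv_filters), function(i) {
    make_conv_plan(H, W, d$kernel, d$dilation)
  })
  params <- withr_seed(seed, {
    p <- list()
    for (br in c("eeg", "meg")) {
      cin <- 1
      for (li in seq_along(d$conv_filters)) {
        cout <- d$conv_filters[li]
        fan_in <- d$kernel^2 * cin
        p[[paste0(br, "_conv", li, "_W")]] <-
          matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
        p[[paste0(br, "_conv", li, "_b")]] <- numeric(cout)
        cin <- cout
      }
      cl <- d$conv_filters[length(d$conv_filters)]
      cr <- cl / d$reduction
      g1 <- sqrt(6 / (cl + cr))
      p[[paste0(br, "_att_W1")]] <- matrix(stats::runif(cr * cl, -g1, g1), cr, cl)
      p[[paste0(br, "_att_W2")]] <- matrix(stats::runif(cl * cr, -g1, g1), cl, cr)
    }
    feat <- 2 * H * W * d$conv_filters[length(d$conv_filters)]
    p$fc1_W <- matrix(stats::rnorm(d$fc_hidden * feat, sd = sqrt(2 / feat)),
                      d$fc_hidden, feat)
    p$fc1_b <- numeric(d$fc_hidden)
    p$out_W <- matrix(stats::rnorm(d$n_out * d$fc_hidden, sd = sqrt(2 / d$fc_hidden)),
                      d$n_out, d$fc_hidden)
    p$out_b <- numeric(d$n_out)
    p
  })
  structure(list(descriptor = d, params = params, plans = plans),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  d <- x$descriptor
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<fusion_model> %dx%d input, conv [%s] k=%d dil=%d, r=%d, fc %d -> %d (%s params)\n",
    d$grid[1], d$grid[2], paste(d$conv_filters, collapse = ","), d$kernel,
    d$dilation, d$reduction, d$fc_hidden, d$n_out, format(np, big.mark = ",")
  ))
  invisible(x)
}

# ---- convolution plumbing ---------------------------------------------------

# precompute im2col gather indices for 'same' dilated convolution
make_conv_plan <- function(H, W, k, dilation) {
  pad <- dilation * (k - 1) / 2
  if (pad != round(pad)) stop("kernel/dilation combination has no 'same' padding")
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  offs <- (seq_len(k) - 1 - (k - 1) / 2) * dilation
  # output pixel (i, j) -> padded pixel (i + pad + dy, j + pad + dx)
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  idx <- matrix(0L, k * k, H * W)
  t <- 0L
  for (dx in offs) for (dy in offs) {
    t <- t + 1L
    idx[t, ] <- (oj + pad + dx - 1) * Hp + (oi + pad + dy)
  }
  list(H = H, W = W, k = k, pad = pad, Hp = Hp, Wp = Wp,
       idx = as.integer(idx), taps = k * k)
}

# X: [H, W, Cin, B] -> list(Y = [H, W, Cout, B], cols = cached im2col matrix)
conv_forward <- function(X, Wmat, b, plan) {
  dm <- dim(X)
  Cin <- dm[3]; B <- dm[4]
  Xp <- array(0, c(plan$Hp, plan$Wp, Cin, B))
  Xp[plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), , ] <- X
  dim(Xp) <- c(plan$Hp * plan$Wp, Cin * B)
  cols <- Xp[plan$idx, , drop = FALSE]                 # (taps*HW) x (Cin*B)
  dim(cols) <- c(plan$taps, plan$H * plan$W, Cin, B)
  cols <- aperm(cols, c(1, 3, 2, 4))                   # taps, Cin, HW, B
  dim(cols) <- c(plan$taps * Cin, plan$H * plan$W * B)
  Y <- Wmat %*% cols + b                               # Cout x (HW*B)
  Cout <- nrow(Wmat)
  dim(Y) <- c(Cout, plan$H * plan$W, B)
  Y <- aperm(Y, c(2, 1, 3))
  dim(Y) <- c(plan$H, plan$W, Cout, B)
  list(Y = Y, cols = cols)
}

# gradients of conv_forward; dY: [H, W, Cout, B]
conv_backward <- function(dY, cols, Wmat, plan, Cin, B) {
  Cout <- nrow(Wmat)
  dim(dY) <- c(plan$H * plan$W, Cout, B)
  dY <- aperm(dY, c(2, 1, 3))
  dim(dY) <- c(Cout, plan$H * plan$W * B)
  dW <- tcrossprod(dY, cols)                           # Cout x (taps*Cin)
  db <- rowSums(dY)
  dcols <- crossprod(Wmat, dY)                         # (taps*Cin) x (HW*B)
  dim(dcols) <- c(plan$taps, Cin, plan$H * plan$W, B)
  dcols <- aperm(dcols, c(1, 3, 2, 4))
  dim(dcols) <- c(plan$taps * plan$H * plan$W, Cin * B)
  acc <- rowsum(dcols, group = plan$idx)               # sums duplicate targets
  dXp <- matrix(0, plan$Hp * plan$Wp, Cin * B)
  dXp[as.integer(rownames(acc)), ] <- acc
  dim(dXp) <- c(plan$Hp, plan$Wp, Cin, B)
  dX <- dXp[plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), , , drop = FALSE]
  list(dW = dW, db = db, dX = dX)
}

# ---- attention --------------------------------------------------------------

#' Channel descriptors by global average pooling
#'
#' @param U Feature maps: 4-D array `[H, W, C, B]`, a 3-D `[H, W, C]` array,
#'   or a list of C matrices (single sample).
#' @return C x B matrix (or length-C vector for a single sample) of per-map
#'   means.
#' @export
channel_descriptors <- function(U) {
  if (is.list(U)) {
    return(vapply(U, function(u) mean(u), numeric(1)))
  }
  dm <- dim(U)
  if (length(dm) == 3) dim(U) <- c(dm, 1L)
  dm <- dim(U)
  m <- matrix(U, dm[1] * dm[2], dm[3] * dm[4])
  z <- matrix(colMeans(m), dm[3], dm[4])
  if (dm[4] == 1) drop(z) else z
}

#' Attention weights from channel descriptors
#'
#' `w = sigmoid(W2 relu(W1 z))`: a two-layer bottleneck (reduction ratio r)
#' turning the C descriptors into C gates in (0, 1).
#'
#' @param z Length-C descriptor vector (or C x B matrix).
#' @param W1 (C/r) x C weight matrix.
#' @param W2 C x (C/r) weight matrix.
#' @return Gates with the same shape as `z`, all entries in (0, 1).
#' @export
attention_weights <- function(z, W1, W2) {
  zm <- if (is.null(dim(z))) matrix(z, ncol = 1) else z
  if (ncol(W1) != nrow(zm)) stop("shape mismatch between `W1` and `z`")
  if (ncol(W2) != nrow(W1)) stop("shape mismatch between `W1` and `W2`")
  a <- W2 %*% pmax(W1 %*% zm, 0)
  w <- 1 / (1 + exp(-a))
  if (is.null(dim(z))) drop(w) else w
}

#' Apply attention gates to feature maps
#'
#' Scales each feature map by its gate: `u_c <- w_c u_c`.
#'
#' @param U Feature maps (`[H, W, C, B]` array, `[H, W, C]` array, or list of
#'   C matrices).
#' @param w Gates (length C, or C x B matching `U`).
#' @return Weighted feature maps, same shape as `U`.
#' @export
apply_attention <- function(U, w) {
  if (is.list(U)) {
    if (length(w) != length(U)) stop("length of `w` must match number of maps")
    return(mapply(function(u, wc) u * wc, U, w, SIMPLIFY = FALSE))
  }
  dm <- dim(U)
  was3 <- length(dm) == 3
  if (was3) { dim(U) <- c(dm, 1L); dm <- dim(U) }
  wm <- if (is.null(dim(w))) matrix(w, dm[3], dm[4]) else w
  if (!all(dim(wm) == dm[3:4])) stop("gate shape does not match feature maps")
  out <- matrix(U, dm[1] * dm[2], dm[3] * dm[4]) *
    rep(as.vector(wm), each = dm[1] * dm[2])
  dim(out) <- dm
  if (was3) dim(out) <- dm[1:3]
  out
}

# one branch forward; x: [H, W, 1, B]; returns activations cache
branch_forward <- function(x, params, plans, prefix, descriptor) {
  cache <- list(x = x)
  A <- x
  for (li in seq_along(descriptor$conv_filters)) {
    cf <- conv_forward(A, params[[paste0(prefix, "_conv", li, "_W")]],
                       params[[paste0(prefix, "_conv", li, "_b")]], plans[[li]])
    cache[[paste0("cols", li)]] <- cf$cols
    cache[[paste0("pre", li)]] <- cf$Y
    A <- pmax(cf$Y, 0)
    cache[[paste0("act", li)]] <- A
  }
  z <- channel_descriptors(A)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  W1 <- params[[paste0(prefix, "_att_W1")]]
  W2 <- params[[paste0(prefix, "_att_W2")]]
  a1 <- W1 %*% z
  h <- pmax(a1, 0)
  a2 <- W2 %*% h
  w <- 1 / (1 + exp(-a2))
  V <- apply_attention(A, w)
  dm <- dim(V)
  f <- matrix(V, dm[1] * dm[2] * dm[3], dm[4]) # flatten
  cache$z <- z; cache$a1 <- a1; cache$h <- h; cache$w <- w
  cache$U <- A; cache$f <- f
  cache
}

#' Forward pass of the fusion model
#'
#' @param model A [fusion_model()].
#' @param x_eeg,x_meg Input matrices: `input_matrix` objects, plain rows x
#'   cols matrices, or `[H, W, B]` / `(H*W) x B` batches.
#' @param cache Return intermediate activations (used by training)?
#' @return N x B matrix of source amplitude estimates (drops to a vector for
#'   a single sample), or the full cache list when `cache = TRUE`.
#' @export
fusion_forward <- function(model, x_eeg, x_meg, cache = FALSE) {
  d <- model$descriptor
  xe <- as_input_batch(x_eeg, d$grid)
  xm <- as_input_batch(x_meg, d$grid)
  if (dim(xe)[4] != dim(xm)[4]) stop("EEG and MEG batches differ in size")

  ce <- branch_forward(xe, model$params, model$plans, "eeg", d)
  cm <- branch_forward(xm, model$params, model$plans, "meg", d)
  f <- rbind(ce$f, cm$f)
  a_fc <- model$params$fc1_W %*% f + model$params$fc1_b
  h_fc <- pmax(a_fc, 0)
  s_hat <- model$params$out_W %*% h_fc + model$params$out_b

  if (cache) {
    return(list(eeg = ce, meg = cm, f = f, a_fc = a_fc, h_fc = h_fc,
                s_hat = s_hat))
  }
  if (ncol(s_hat) == 1) drop(s_hat) else s_hat
}

# coerce the accepted input forms to [H, W, 1, B]
as_input_batch <- function(x, grid) {
  if (inherits(x, "input_matrix")) x <- x$values
  H <- grid[1]; W <- grid[2]
  if (is.null(dim(x))) {
    if (length(x) != H * W) stop("input length does not match the model grid")
    dim(x) <- c(H, W)
  }
  dm <- dim(x)
  if (length(dm) == 2) {
    if (all(dm == c(H, W))) {
      dim(x) <- c(H, W, 1, 1)
    } else if (dm[1] == H * W) {
      dim(x) <- c(H, W, 1, dm[2])     # (H*W) x B, column-major cells
    } else {
      stop("input matrix shape does not match the model grid")
    }
  } else if (length(dm) == 3) {
    if (!all(dm[1:2] == c(H, W))) stop("input array shape does not match the model grid")
    dim(x) <- c(H, W, 1, dm[3])
  } else stop("unsupported input shape")
  x
}
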