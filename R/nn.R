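# Minimal 3D convolutional-network primitives on base R matrices.
#
# A batch of feature maps is a single numeric matrix whose rows are
# spatial positions (column-major over the grid) stacked batch-sample by
# batch-sample, and whose columns are channels.  Valid 3x3x3
# convolutions are lowered to a gather (im2col) followed by one BLAS
# matrix product for the whole batch; the data gradient is the
# transposed convolution, again a gather plus one product.  Gather
# indices depend only on the geometry, so they are built once and
# cached.  Everything needed for training (gradients, Adam) lives here;
# no external framework is used.

KERNEL <- 3L

.nn_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  v <- .nn_cache[[key]]
  if (is.null(v)) {
    v <- build()
    .nn_cache[[key]] <- v
  }
  v
}

# Row map for nearest-neighbour upsampling by factor f: for each
# upsampled row, the source row in the low-resolution matrix.
bt_upsample_rows <- function(lo, B, f) {
  key <- paste("ups", paste(lo, collapse = "x"), B, f, sep = "|")
  cache_get(key, function() {
    hi <- lo * f
    ux <- rep(seq_len(lo[1]), each = f)
    uy <- rep(seq_len(lo[2]), each = f)
    uz <- rep(seq_len(lo[3]), each = f)
    base <- as.vector(outer(outer(ux, (uy - 1L) * lo[1], "+"),
                            (uz - 1L) * lo[1] * lo[2], "+"))
    as.integer(rep(base, times = B) +
                 rep((seq_len(B) - 1L) * prod(lo), each = prod(hi)))
  })
}

# ---- batched layer ops ---------------------------------------------------

btconv3_forward <- function(x, sdim, B, W, b) {
  col <- cpp_im2col3(x, as.integer(sdim), as.integer(B))
  y <- col %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = y, col = col, sdim = sdim, cin = ncol(x))
}

# Rearrange W (27*cin, cout) into the transposed-convolution kernel
# (27*cout, cin) with spatially flipped offsets.
rotate_kernel <- function(W, cin, cout) {
  Wa <- array(W, c(cin, 27L, cout))
  Wa <- Wa[, 27:1, , drop = FALSE]
  matrix(aperm(Wa, c(3L, 2L, 1L)), 27L * cout, cin)
}

btconv3_backward <- function(dy, cache, W, B, want_dx = TRUE) {
  dW <- crossprod(cache$col, dy)
  db <- colSums(dy)
  if (!want_dx) return(list(dW = dW, db = db, dx = NULL))
  od <- cache$sdim - (KERNEL - 1L)
  cout <- ncol(dy)
  colp <- cpp_im2col3_padded(dy, as.integer(od), as.integer(B))
  dx <- colp %*% rotate_kernel(W, cache$cin, cout)
  list(dW = dW, db = db, dx = dx)
}

# 1^3 convolution = per-position dense layer (already a plain matrix op).
btconv1_forward <- function(x, W, b) {
  y <- x %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = y, x = x)
}

btconv1_backward <- function(dy, cache, W) {
  list(dW = crossprod(cache$x, dy),
       db = colSums(dy),
       dx = tcrossprod(dy, W))
}

LRELU_SLOPE <- 0.01

lrelu_forward <- function(x) {
  neg <- x < 0
  x[neg] <- x[neg] * LRELU_SLOPE
  list(y = x, neg = neg)
}

lrelu_backward <- function(dy, cache) {
  dy[cache$neg] <- dy[cache$neg] * LRELU_SLOPE
  dy
}

bt_upsample <- function(x, lo, B, f) {
  x[bt_upsample_rows(lo, B, f), , drop = FALSE]
}

bt_upsample_backward <- function(dy, lo, B, f) {
  rs <- rowsum(dy, group = bt_upsample_rows(lo, B, f))
  # rowsum orders by group value, which here is 1..prod(lo)*B: complete
  # because every low-res row is used
  rs
}

# Non-overlapping mean pooling by integer factor f on a single 4D array
# (applied to input data only; no gradient needed).
mean_pool3 <- function(x, f) {
  d <- dim(x)
  stopifnot(all(d[1:3] %% f == 0))
  od <- d[1:3] %/% f
  out <- array(0, c(od, d[4]))
  for (a in 0:(f - 1)) for (b in 0:(f - 1)) for (cc in 0:(f - 1)) {
    out <- out + x[seq(1L + a, d[1], f), seq(1L + b, d[2], f),
                   seq(1L + cc, d[3], f), , drop = FALSE]
  }
  out / f^3
}

# Stack a list of 4D patches (x, y, z, channel) into one batched
# feature matrix (positions x batch rows, channel columns).
bt_stack <- function(patches) {
  B <- length(patches)
  d <- dim(patches[[1]])
  npos <- prod(d[1:3])
  arr <- array(0, c(npos, B, d[4]))
  for (b in seq_len(B)) arr[, b, ] <- patches[[b]]
  dim(arr) <- c(npos * B, d[4])
  arr
}

softmax_rows <- function(logits) {
  m <- logits - pmax(logits[, 1L], logits[, 2L])   # 2-class, row-stable
  e <- exp(m)
  e / rowSums(e)
}

#' Soft Dice loss
#'
#' \code{1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)} over the
#' foreground class, averaged over the patches of a batch when given
#' lists.
#'
#' @param prob Foreground-probability array (or list of arrays).
#' @param label Binary label array of the same length (or list).
#' @param eps Smoothing constant (default 1e-5).
#' @return Scalar loss in [0, 1 + eps].
#' @export
dice_loss <- function(prob, label, eps = 1e-5) {
  if (is.list(prob)) {
    stopifnot(length(prob) == length(label))
    return(mean(mapply(dice_loss, prob, label,
                       MoreArgs = list(eps = eps))))
  }
  stopifnot(length(prob) == length(label))
  p <- as.numeric(prob)
  y <- as.numeric(label)
  1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
}

# Gradient of the per-patch soft Dice loss wrt the 2-class logits,
# through the softmax.  prob: 2-column matrix; label: vector.
dice_loss_grad_logits <- function(prob, label, eps = 1e-5) {
  p1 <- prob[, 2L]
  p0 <- prob[, 1L]
  y <- as.numeric(label)
  num <- 2 * sum(p1 * y) + eps
  den <- sum(p1) + sum(y) + eps
  dLdp1 <- -(2 * y * den - num) / den^2
  g1 <- dLdp1 * p1 * p0                       # p1 * (1 - p1) = p1 * p0
  cbind(-g1, g1, deparse.level = 0)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
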