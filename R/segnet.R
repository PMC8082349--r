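# Dual-pathway patch-based 3D segmentation network and its training
# protocol.  A normal-resolution pathway sees a central crop of the
# input window; a subsampled pathway sees the whole window mean-pooled
# by the downsample factor, and its features are upsampled and
# concatenated before the fully-connected (1^3 convolution) head.
# Training minimizes a soft Dice loss with Adam under a stepped
# learning-rate schedule; the sparsified-training augmentation randomly
# zero-fills secondary channels of each sampled patch stack.

#' Network architecture configuration
#'
#' Geometry rule (valid 3^3 convolutions, no padding): the subsampled
#' pathway sees the \code{input_patch} window mean-pooled by
#' \code{downsample_factor}, loses \code{2 * conv_layers} voxels per
#' axis to the convolutions, and is upsampled back by the factor, so
#' \deqn{output = (input/ds - 2 L) \cdot ds}
#' while the normal pathway's input crop is \code{output + 2 L}.  The
#' default preset (input 57^3, factor 3, 8 conv layers per pathway)
#' yields a 9^3 output and, with its two 150-wide 1^3 layers and the
#' classifier, 11 weighted layers.
#'
#' @param preset "paper" (the full-size network) or "tiny" (a small
#'   CPU-friendly network with the same topology: 3 conv layers of
#'   8, 8, 16 maps, one 32-wide head layer, input 27^3).
#' @param n_channels Number of input channels (4).
#' @param conv_layers_per_pathway,feature_maps,fc_layers,downsample_factor,input_patch
#'   Overrides for the preset values.
#' @return A list of class \code{net_config} including the derived
#'   \code{output_patch}, \code{high_in} and \code{low_in} sizes.
#' @export
net_config <- function(preset = c("paper", "tiny"),
                       n_channels = 4L,
                       conv_layers_per_pathway = NULL,
                       feature_maps = NULL,
                       fc_layers = NULL,
                       downsample_factor = NULL,
                       input_patch = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") {
    list(conv_layers_per_pathway = 8L,
         feature_maps = c(30L, 30L, 40L, 40L, 40L, 40L, 50L, 50L),
         fc_layers = c(150L, 150L),
         downsample_factor = 3L,
         input_patch = 57L)
  } else {
    list(conv_layers_per_pathway = 3L,
         feature_maps = c(8L, 8L, 16L),
         fc_layers = 32L,
         downsample_factor = 3L,
         input_patch = 27L)
  }
  L <- as.integer(conv_layers_per_pathway %||% def$conv_layers_per_pathway)
  fm <- as.integer(feature_maps %||% def$feature_maps)
  fc <- as.integer(fc_layers %||% def$fc_layers)
  ds <- as.integer(downsample_factor %||% def$downsample_factor)
  ip <- as.integer(input_patch %||% def$input_patch)
  if (length(fm) != L)
    stop("feature_maps must list one width per conv layer (", L, ")")
  if (ds < 1L) stop("downsample_factor must be >= 1")
  if (ip %% ds != 0L)
    stop("invalid geometry: input_patch ", ip,
         " is not divisible by downsample factor ", ds)
  low_in <- ip %/% ds
  out_low <- low_in - 2L * L
  if (out_low < 1L)
    stop("invalid geometry: pooled window ", low_in,
         "^3 is consumed by ", L, " convolutions (would leave ",
         out_low, "^3)")
  output <- out_low * ds
  high_in <- output + 2L * L
  if (high_in > ip)
    stop("invalid geometry: normal-pathway crop ", high_in,
         "^3 exceeds the input window ", ip, "^3")
  if (ip %% 2L == 0L || output %% 2L == 0L)
    stop("invalid geometry: input (", ip, ") and output (", output,
         ") patch sizes must be odd for centered sampling")
  structure(list(preset = preset,
                 n_channels = as.integer(n_channels),
                 conv_layers_per_pathway = L,
                 feature_maps = fm,
                 fc_layers = fc,
                 downsample_factor = ds,
                 input_patch = ip,
                 output_patch = output,
                 high_in = high_in,
                 low_in = low_in,
                 n_weighted_layers = L + length(fc) + 1L),
            class = "net_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.net_config <- function(x, ...) {
  cat("<net_config> preset=", x$preset,
      ": input ", x$input_patch, "^3, downsample ", x$downsample_factor,
      ", output ", x$output_patch, "^3\n", sep = "")
  cat("  pathways: ", x$conv_layers_per_pathway, " conv layers (",
      paste(x$feature_maps, collapse = ","), " maps), crops ",
      x$high_in, "^3 / ", x$low_in, "^3; head ",
      paste(x$fc_layers, collapse = ","), "; ",
      x$n_weighted_layers, " weighted layers\n", sep = "")
  invisible(x)
}

#' Training-loop configuration
#'
#' @param preset "paper" (30 000 iterations, 32 patches/iteration) or
#'   "tiny" (500 iterations, 8 patches/iteration).
#' @param iterations,batch_size,lr0,sparsify_p,fg_fraction,seed Overrides.
#'   \code{sparsify_p} is the independent per-channel probability that a
#'   secondary channel of a sampled patch stack is zero-filled (0.2);
#'   \code{fg_fraction} is the fraction of patch centers drawn from the
#'   tumor core rather than uniformly from the brain (0.5).
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(preset = c("paper", "tiny"),
                         iterations = NULL, batch_size = NULL,
                         lr0 = 0.001, sparsify_p = 0.2,
                         fg_fraction = 0.5, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") list(iterations = 30000L, batch_size = 32L)
         else list(iterations = 500L, batch_size = 8L)
  if (sparsify_p < 0 || sparsify_p > 1)
    stop("sparsify_p must lie in [0, 1]")
  structure(list(preset = preset,
                 iterations = as.integer(iterations %||% def$iterations),
                 batch_size = as.integer(batch_size %||% def$batch_size),
                 lr0 = lr0, sparsify_p = sparsify_p,
                 fg_fraction = fg_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' The rate starts at \code{lr0} and is divided by 2 every 5000
#' iterations up to iteration 15 000 and every 1500 iterations
#' thereafter (piecewise-constant, nonincreasing).
#'
#' @param iteration 0-based iteration index.
#' @param config A \code{\link{train_config}} (only \code{lr0} is used).
#' @return The learning rate at that iteration.
#' @export
lr_schedule <- function(iteration, config = train_config("paper")) {
  stopifnot(all(iteration >= 0))
  halvings <- pmin(iteration, 15000) %/% 5000 +
    pmax(0, iteration - 15000) %/% 1500
  config$lr0 / 2^halvings
}

# ---- sparsification ------------------------------------------------------

#' Randomly zero-fill secondary channels of a patch stack
#'
#' Each secondary channel (T1w, T2w, FLAIR) is independently replaced by
#' zeros with probability \code{p}; the primary channel (index 1) is
#' never touched.  Already-zero channels are unchanged, so the operation
#' is idempotent.  When \code{patch} is a sampled pair (list with
#' \code{high} and \code{low} stacks), one draw is shared by both stacks
#' so the two pathways always see the same availability.
#'
#' @param patch A 4D array (x, y, z, channel) or a list with elements
#'   \code{high} and \code{low} holding such arrays.
#' @param p Per-channel zeroing probability.
#' @param draws Optional logical vector of length 3 (one per secondary
#'   channel) overriding the random draw.
#' @return The sparsified patch, same type as the input.
#' @export
sparsify_channels <- function(patch, p, draws = NULL) {
  if (is.null(draws)) draws <- stats::runif(3) < p
  stopifnot(length(draws) == 3L)
  zero_ch <- function(stack) {
    for (i in which(draws)) stack[, , , i + 1L] <- 0
    stack
  }
  if (is.list(patch)) {
    patch$high <- zero_ch(patch$high)
    patch$low <- zero_ch(patch$low)
    patch
  } else zero_ch(patch)
}

# ---- patch sampling ------------------------------------------------------

# Zero-padded odd-sized window extraction around a voxel center.
extract_window <- function(arr, center, size) {
  half <- (size - 1L) %/% 2L
  out <- array(0, rep(size, 3L))
  lo <- center - half
  hi <- center + half
  slo <- pmax(lo, 1L)
  shi <- pmin(hi, dim(arr))
  if (any(slo > shi)) return(out)
  olo <- slo - lo + 1L
  ohi <- olo + (shi - slo)
  out[olo[1]:ohi[1], olo[2]:ohi[2], olo[3]:ohi[3]] <-
    arr[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]]
  out
}

subject_stack <- function(subject) {
  dims <- dim(subject$channels[[1]])
  arr <- array(0, c(dims, 4L))
  for (i in seq_along(channel_names()))
    arr[, , , i] <- subject$channels[[channel_names()[i]]]
  arr
}

# Zero-padded window over all channels of a 4D stack in one slice.
stack_windows <- function(stack, center, size) {
  d <- dim(stack)
  half <- (size - 1L) %/% 2L
  out <- array(0, c(rep(size, 3L), d[4]))
  lo <- center - half
  hi <- center + half
  slo <- pmax(lo, 1L)
  shi <- pmin(hi, d[1:3])
  if (any(slo > shi)) return(out)
  olo <- slo - lo + 1L
  ohi <- olo + (shi - slo)
  out[olo[1]:ohi[1], olo[2]:ohi[2], olo[3]:ohi[3], ] <-
    stack[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3], , drop = FALSE]
  out
}

#' Sample one training patch pair from a subject
#'
#' With probability \code{fg_fraction} the patch center is drawn
#' uniformly from the tumor core (falling back to the brain if the mask
#' is empty), otherwise uniformly from the brain mask.  The
#' normal-pathway stack is the central \code{high_in}^3 crop of the
#' \code{input_patch}^3 window; the subsampled-pathway stack is the
#' whole window mean-pooled by the downsample factor; the label patch is
#' the central \code{output_patch}^3 crop of the mask.  Out-of-volume
#' context is zero-padded.  Uses the current RNG state.
#'
#' @param subject A normalized \code{\link{mri_subject}} with a mask.
#' @param net_cfg A \code{\link{net_config}}.
#' @param fg_fraction Foreground-centered sampling probability.
#' @param cache Optional precomputed list from
#'   \code{subject_patch_cache}.
#' @return List with \code{high}, \code{low} (4D stacks), \code{label}
#'   (3D array) and \code{center}.
#' @export
sample_patch <- function(subject, net_cfg, fg_fraction = 0.5,
                         cache = NULL) {
  if (is.null(cache)) cache <- subject_patch_cache(subject)
  use_fg <- stats::runif(1) < fg_fraction && length(cache$fg_idx) > 0
  idx_pool <- if (use_fg) cache$fg_idx else cache$brain_idx
  center <- as.integer(
    arrayInd(idx_pool[sample.int(length(idx_pool), 1L)], cache$dims))
  patch_at(subject, center, net_cfg, cache)
}

#' Precompute per-subject sampling indices and the channel stack
#' @param subject An \code{\link{mri_subject}}.
#' @return List with the stacked channels and candidate center indices.
#' @export
subject_patch_cache <- function(subject) {
  list(stack = subject_stack(subject),
       fg_idx = if (!is.null(subject$mask)) which(subject$mask == 1)
                else integer(0),
       brain_idx = which(subject$brain_mask == 1),
       dims = dim(subject$brain_mask))
}

patch_at <- function(subject, center, net_cfg, cache = NULL) {
  if (is.null(cache)) cache <- subject_patch_cache(subject)
  window <- stack_windows(cache$stack, center, net_cfg$input_patch)
  crop0 <- (net_cfg$input_patch - net_cfg$high_in) %/% 2L
  hi_idx <- (crop0 + 1L):(crop0 + net_cfg$high_in)
  high <- window[hi_idx, hi_idx, hi_idx, , drop = FALSE]
  low <- mean_pool3(window, net_cfg$downsample_factor)
  label <- if (!is.null(subject$mask))
    extract_window(subject$mask, center, net_cfg$output_patch) else NULL
  list(high = high, low = low, label = label, center = center)
}

# ---- network construction and passes -------------------------------------

#' Build (initialize) the dual-pathway network
#'
#' He-style initialization (normal with SD \code{sqrt(2 / fan_in)}),
#' deterministic given the seed.  The two pathways share their topology
#' but have separate weights.  Construction asserts the geometry
#' self-check: per axis, output size equals pathway input minus
#' \code{conv_layers * (kernel - 1)}.
#'
#' @param net_cfg A \code{\link{net_config}}.
#' @param seed Integer seed for the initialization.
#' @return List with the flat parameter list and the parameter count.
#' @export
build_network <- function(net_cfg, seed = 1L) {
  # geometry self-check (net_config already validated; assert anyway)
  L <- net_cfg$conv_layers_per_pathway
  stopifnot(net_cfg$output_patch == net_cfg$high_in - L * (KERNEL - 1L),
            net_cfg$output_patch ==
              (net_cfg$low_in - L * (KERNEL - 1L)) *
                net_cfg$downsample_factor)
  set.seed(as.integer(seed))
  params <- list()
  he <- function(fan_in, fan_out) {
    matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
           fan_in, fan_out)
  }
  widths <- c(net_cfg$n_channels, net_cfg$feature_maps)
  for (path in c("high", "low")) {
    for (l in seq_len(L)) {
      fan_in <- 27L * widths[l]
      params[[paste0(path, l, ".W")]] <- he(fan_in, widths[l + 1L])
      params[[paste0(path, l, ".b")]] <- numeric(widths[l + 1L])
    }
  }
  head_widths <- c(2L * net_cfg$feature_maps[L], net_cfg$fc_layers)
  for (l in seq_along(net_cfg$fc_layers)) {
    params[[paste0("fc", l, ".W")]] <- he(head_widths[l],
                                          head_widths[l + 1L])
    params[[paste0("fc", l, ".b")]] <- numeric(head_widths[l + 1L])
  }
  last <- head_widths[length(head_widths)]
  params[["cls.W"]] <- he(last, 2L)
  params[["cls.b"]] <- numeric(2L)
  n_params <- sum(vapply(params, length, numeric(1)))
  list(params = params, n_params = n_params)
}

# Batched forward pass: Xh / Xl are batched feature matrices (see nn.R)
# over the high-res crop / pooled window grids; B is the batch size.
net_forward_batch <- function(params, net_cfg, Xh, Xl, B,
                              want_cache = FALSE) {
  L <- net_cfg$conv_layers_per_pathway
  caches <- list()
  sdims <- list(high = rep(net_cfg$high_in, 3L),
                low = rep(net_cfg$low_in, 3L))
  feats <- list(high = Xh, low = Xl)
  for (path in c("high", "low")) {
    x <- feats[[path]]
    sd <- sdims[[path]]
    for (l in seq_len(L)) {
      cv <- btconv3_forward(x, sd, B, params[[paste0(path, l, ".W")]],
                            params[[paste0(path, l, ".b")]])
      ac <- lrelu_forward(cv$y)
      x <- ac$y
      sd <- sd - (KERNEL - 1L)
      if (want_cache)
        caches[[paste0(path, l)]] <- list(conv = cv, act = ac)
    }
    feats[[path]] <- x
  }
  out_low <- rep(net_cfg$output_patch %/% net_cfg$downsample_factor, 3L)
  up <- bt_upsample(feats$low, out_low, B, net_cfg$downsample_factor)
  x <- cbind(feats$high, up, deparse.level = 0)
  for (l in seq_along(net_cfg$fc_layers)) {
    cv <- btconv1_forward(x, params[[paste0("fc", l, ".W")]],
                          params[[paste0("fc", l, ".b")]])
    ac <- lrelu_forward(cv$y)
    x <- ac$y
    if (want_cache) caches[[paste0("fc", l)]] <- list(conv = cv, act = ac)
  }
  cv <- btconv1_forward(x, params[["cls.W"]], params[["cls.b"]])
  if (want_cache) caches[["cls"]] <- list(conv = cv)
  prob <- softmax_rows(cv$y)
  list(logits = cv$y, prob = prob, caches = caches,
       n_feat = ncol(feats$high), B = B)
}

net_backward_batch <- function(params, net_cfg, fwd, dlogits) {
  B <- fwd$B
  grads <- list()
  bk <- btconv1_backward(dlogits, fwd$caches[["cls"]]$conv,
                         params[["cls.W"]])
  grads[["cls.W"]] <- bk$dW
  grads[["cls.b"]] <- bk$db
  dx <- bk$dx
  for (l in rev(seq_along(net_cfg$fc_layers))) {
    cache <- fwd$caches[[paste0("fc", l)]]
    dx <- lrelu_backward(dx, cache$act)
    bk <- btconv1_backward(dx, cache$conv, params[[paste0("fc", l, ".W")]])
    grads[[paste0("fc", l, ".W")]] <- bk$dW
    grads[[paste0("fc", l, ".b")]] <- bk$db
    dx <- bk$dx
  }
  nf <- fwd$n_feat
  out_low <- rep(net_cfg$output_patch %/% net_cfg$downsample_factor, 3L)
  dpath <- list(high = dx[, seq_len(nf), drop = FALSE],
                low = bt_upsample_backward(
                  dx[, nf + seq_len(nf), drop = FALSE],
                  out_low, B, net_cfg$downsample_factor))
  L <- net_cfg$conv_layers_per_pathway
  for (path in c("high", "low")) {
    dx <- dpath[[path]]
    for (l in rev(seq_len(L))) {
      cache <- fwd$caches[[paste0(path, l)]]
      dx <- lrelu_backward(dx, cache$act)
      bk <- btconv3_backward(dx, cache$conv,
                             params[[paste0(path, l, ".W")]], B,
                             want_dx = l > 1L)  # layer-1 input is data
      grads[[paste0(path, l, ".W")]] <- bk$dW
      grads[[paste0(path, l, ".b")]] <- bk$db
      dx <- bk$dx
    }
  }
  grads
}

# Single-sample convenience wrappers over the batched pass (4D arrays
# in, probability array over the output patch out).
net_forward <- function(params, net_cfg, high, low, want_cache = FALSE) {
  fwd <- net_forward_batch(params, net_cfg, bt_stack(list(high)),
                           bt_stack(list(low)), 1L,
                           want_cache = want_cache)
  op <- rep(net_cfg$output_patch, 3L)
  fwd$prob_arr <- array(fwd$prob, c(op, 2L))
  fwd
}

net_backward <- function(params, net_cfg, fwd, dlogits) {
  net_backward_batch(params, net_cfg, fwd,
                     matrix(dlogits, ncol = 2L))
}

# ---- training ------------------------------------------------------------

#' Fit the segmentation network
#'
#' Trains the dual-pathway network on a list of subjects with Adam, the
#' stepped learning-rate schedule and a soft Dice loss; the weights of
#' the last iteration are the deliverable (no early stopping or
#' validation-based selection).  With \code{sparsified = TRUE}, each
#' sampled patch stack passes through \code{\link{sparsify_channels}}
#' after normalization, so augmented-missing channels reach the network
#' exactly as originally-missing ones do.
#'
#' Patch sampling and sparsification draw from two separate seeded
#' streams derived from \code{train_cfg$seed}, so a pair of models
#' differing only in \code{sparsified} sees the identical initial
#' weights and patch sequence, and \code{sparsified = TRUE} with
#' \code{sparsify_p = 0} is run-for-run identical to
#' \code{sparsified = FALSE}.
#'
#' @param subjects Training subjects (raw; normalized internally unless
#'   \code{normalize = FALSE}).
#' @param net_cfg A \code{\link{net_config}}.
#' @param train_cfg A \code{\link{train_config}}.
#' @param sparsified Enable the sparsified-training augmentation.
#' @param hist_model Optional pre-fit \code{\link{fit_histogram_model}}
#'   result; fitted on \code{subjects} (before any augmentation) when
#'   NULL and \code{normalize} is TRUE.
#' @param normalize Normalize the subjects internally (default TRUE;
#'   set FALSE if they are already normalized).
#' @param verbose Print progress every 100 iterations.
#' @return An object of class \code{sparseseg}.
#' @export
sparseseg <- function(subjects, net_cfg = net_config("tiny"),
                      train_cfg = train_config("tiny"),
                      sparsified = TRUE, hist_model = NULL,
                      normalize = TRUE, verbose = FALSE) {
  stopifnot(length(subjects) >= 1)
  if (normalize) {
    if (is.null(hist_model)) hist_model <- fit_histogram_model(subjects)
    subjects <- lapply(subjects, normalize_subject, model = hist_model)
  }
  for (s in subjects)
    if (is.null(s$mask)) stop("training subject ", s$subject_id,
                              " has no ground-truth mask")
  caches <- lapply(subjects, subject_patch_cache)
  net <- build_network(net_cfg, seed = derive_seed(train_cfg$seed, 11L))
  params <- net$params
  state <- adam_init(params)
  n_iter <- train_cfg$iterations
  log <- data.frame(iteration = seq_len(n_iter) - 1L,
                    loss = NA_real_, lr = NA_real_)
  for (t in seq_len(n_iter)) {
    lr <- lr_schedule(t - 1L, train_cfg)
    set.seed(derive_seed(train_cfg$seed, 13L, t))
    subj_idx <- sample.int(length(subjects), train_cfg$batch_size,
                           replace = TRUE)
    patches <- lapply(subj_idx, function(i)
      sample_patch(subjects[[i]], net_cfg, train_cfg$fg_fraction,
                   caches[[i]]))
    if (sparsified && train_cfg$sparsify_p > 0) {
      set.seed(derive_seed(train_cfg$seed, 17L, t))
      patches <- lapply(patches, sparsify_channels,
                        p = train_cfg$sparsify_p)
    }
    B <- train_cfg$batch_size
    fwd <- net_forward_batch(params, net_cfg,
                             bt_stack(lapply(patches, `[[`, "high")),
                             bt_stack(lapply(patches, `[[`, "low")),
                             B, want_cache = TRUE)
    onpos <- net_cfg$output_patch^3
    loss_sum <- 0
    dlogits <- matrix(0, nrow(fwd$prob), 2L)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * onpos + seq_len(onpos)
      pb <- fwd$prob[rows, , drop = FALSE]
      loss_sum <- loss_sum + dice_loss(pb[, 2L], patches[[b]]$label)
      dlogits[rows, ] <- dice_loss_grad_logits(pb, patches[[b]]$label) / B
    }
    loss <- loss_sum / B
    if (!is.finite(loss))
      stop("non-finite loss at iteration ", t - 1L,
           " (lr = ", lr, "); aborting")
    grad_sum <- net_backward_batch(params, net_cfg, fwd, dlogits)
    st <- adam_step(params, grad_sum, state, lr)
    params <- st$params
    state <- st$state
    log$loss[t] <- loss
    log$lr[t] <- lr
    if (verbose && (t %% 100L == 0L || t == 1L))
      message(sprintf("iter %5d  loss %.4f  lr %.2e", t - 1L, loss, lr))
  }
  structure(list(params = params, net_cfg = net_cfg,
                 train_cfg = train_cfg, sparsified = sparsified,
                 hist_model = hist_model, log = log,
                 n_params = net$n_params),
            class = "sparseseg")
}

#' @export
print.sparseseg <- function(x, ...) {
  cat("<sparseseg> dual-pathway 3D segmentation network\n")
  cat("  preset: ", x$net_cfg$preset, " (", format(x$n_params, big.mark = ","),
      " parameters); sparsified training: ",
      if (x$sparsified) sprintf("on (p = %.2f)", x$train_cfg$sparsify_p)
      else "off", "\n", sep = "")
  cat("  trained ", nrow(x$log), " iterations; final loss ",
      signif(utils::tail(x$log$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.sparseseg <- function(object, ...) {
  print(object)
  print(object$net_cfg)
  n <- nrow(object$log)
  half <- object$log$loss[seq(max(1, n - 49), n)]
  cat("  mean loss over last 50 iterations: ", signif(mean(half), 4),
      "\n", sep = "")
  invisible(object)
}

#' @export
coef.sparseseg <- function(object, ...) object$params

#' @export
plot.sparseseg <- function(x, ...) {
  graphics::plot(x$log$iteration, x$log$loss, type = "l",
                 xlab = "iteration", ylab = "Dice loss",
                 main = sprintf("training loss (%s)",
                                if (x$sparsified) "sparsified" else "plain"),
                 ...)
  invisible(x)
}

#' Segment a subject with a fitted network
#'
#' Whole-volume inference by dense tiling with stride equal to the
#' output patch: every voxel is predicted exactly once, with zero-padded
#' context at the borders.  Raw subjects are normalized with the model's
#' stored histogram model first; missing channels stay exactly zero.
#'
#' @param object A fitted \code{\link{sparseseg}} model.
#' @param subject An \code{\link{mri_subject}}.
#' @param type "mask" (default) for the argmax segmentation or "prob"
#'   for the foreground-probability volume.
#' @param restrict_to_brain Skip tiles whose output window contains no
#'   brain voxels, leaving them background (default TRUE; the tumor
#'   core lies inside the brain support by construction).
#' @param ... Unused.
#' @return A \code{\link{seg_mask}}, or a numeric array for
#'   \code{type = "prob"}.
#' @export
predict.sparseseg <- function(object, subject, type = c("mask", "prob"),
                              restrict_to_brain = TRUE, ...) {
  type <- match.arg(type)
  if (!isTRUE(attr(subject, "normalized")))
    subject <- normalize_subject(subject, object$hist_model)
  cfg <- object$net_cfg
  dims <- dim(subject$brain_mask)
  cache <- subject_patch_cache(subject)
  out <- array(0, dims)
  op <- cfg$output_patch
  half <- (op - 1L) %/% 2L
  origins <- expand.grid(
    ox = seq(1L, dims[1], by = op),
    oy = seq(1L, dims[2], by = op),
    oz = seq(1L, dims[3], by = op))
  if (restrict_to_brain) {
    # the tumor lies inside the brain support: tiles whose output
    # window misses it entirely stay background
    keep <- vapply(seq_len(nrow(origins)), function(i) {
      o <- as.integer(origins[i, ])
      e <- pmin(o + op - 1L, dims)
      sum(subject$brain_mask[o[1]:e[1], o[2]:e[2], o[3]:e[3]]) > 0
    }, logical(1))
    origins <- origins[keep, , drop = FALSE]
  }
  chunk <- 32L
  onpos <- op^3
  for (s in seq(1L, nrow(origins), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(origins))
    pts <- lapply(rows, function(i)
      patch_at(subject, as.integer(origins[i, ]) + half, cfg, cache))
    fwd <- net_forward_batch(object$params, cfg,
                             bt_stack(lapply(pts, `[[`, "high")),
                             bt_stack(lapply(pts, `[[`, "low")),
                             length(pts))
    for (b in seq_along(rows)) {
      o <- as.integer(origins[rows[b], ])
      p1 <- array(fwd$prob[(b - 1L) * onpos + seq_len(onpos), 2L],
                  rep(op, 3L))
      val <- if (type == "prob") p1 else (p1 > 0.5) * 1
      e <- pmin(o + op - 1L, dims)
      out[o[1]:e[1], o[2]:e[2], o[3]:e[3]] <-
        val[1:(e[1] - o[1] + 1L), 1:(e[2] - o[2] + 1L),
            1:(e[3] - o[3] + 1L)]
    }
  }
  if (type == "prob") return(out)
  seg_mask(out, subject$spacing)
}

# ---- checkpoint serialization --------------------------------------------

#' Save a fitted model (weights + configs) as JSON
#' @param model A \code{sparseseg} model.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_sparseseg <- function(model, path) {
  ser <- list(
    net_cfg = unclass(model$net_cfg),
    train_cfg = unclass(model$train_cfg),
    sparsified = model$sparsified,
    hist_model = unclass(model$hist_model),
    n_params = model$n_params,
    log = model$log,
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted model saved by \code{\link{save_sparseseg}}
#' @param path JSON checkpoint path.
#' @return A \code{sparseseg} model.
#' @export
load_sparseseg <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(raw$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) == 2L) matrix(as.numeric(p$data), d[1], d[2])
    else as.numeric(p$data)
  })
  nc <- raw$net_cfg
  net_cfg <- net_config(nc$preset, n_channels = nc$n_channels,
                        conv_layers_per_pathway = nc$conv_layers_per_pathway,
                        feature_maps = nc$feature_maps,
                        fc_layers = nc$fc_layers,
                        downsample_factor = nc$downsample_factor,
                        input_patch = nc$input_patch)
  tc <- raw$train_cfg
  train_cfg <- train_config(tc$preset, iterations = tc$iterations,
                            batch_size = tc$batch_size, lr0 = tc$lr0,
                            sparsify_p = tc$sparsify_p,
                            fg_fraction = tc$fg_fraction, seed = tc$seed)
  hm <- structure(list(percentiles = as.numeric(raw$hist_model$percentiles),
                       landmarks = lapply(raw$hist_model$landmarks,
                                          as.numeric)),
                  class = "histogram_model")
  structure(list(params = params, net_cfg = net_cfg, train_cfg = train_cfg,
                 sparsified = raw$sparsified, hist_model = hm,
                 log = as.data.frame(raw$log), n_params = raw$n_params),
            class = "sparseseg")
}
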