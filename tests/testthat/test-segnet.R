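test_that("the default preset reproduces the printed patch geometry", {
  cfg <- net_config("paper")
  expect_equal(cfg$input_patch, 57L)
  expect_equal(cfg$downsample_factor, 3L)
  expect_equal(cfg$output_patch, 9L)
  expect_equal(cfg$high_in, 25L)
  expect_equal(cfg$low_in, 19L)
  expect_equal(cfg$n_weighted_layers, 11L)
  tiny <- net_config("tiny")
  expect_equal(tiny$output_patch, 9L)
  expect_equal(tiny$high_in, 15L)
})

test_that("invalid geometries fail at construction with computed sizes", {
  expect_error(net_config("tiny", input_patch = 28L), "not divisible")
  expect_error(net_config("tiny", input_patch = 15L),
               "consumed")
  expect_error(net_config("tiny", feature_maps = c(8L, 8L)),
               "one width per conv layer")
})

test_that("the learning-rate schedule follows the stepped halving rule", {
  tc <- train_config("paper")
  expect_equal(lr_schedule(0L, tc), 0.001)
  expect_equal(lr_schedule(4999L, tc), 0.001)
  expect_equal(lr_schedule(5000L, tc), 0.0005)
  expect_equal(lr_schedule(15000L, tc), 0.001 / 8)
  # independent simulation of the stated rule, iteration by iteration
  lr_sim <- numeric(30000)
  lr <- 0.001
  for (it in 0:29999) {
    if (it > 0) {
      halve <- (it <= 15000 && it %% 5000 == 0) ||
        (it > 15000 && (it - 15000) %% 1500 == 0)
      if (halve) lr <- lr / 2
    }
    lr_sim[it + 1] <- lr
  }
  expect_equal(lr_schedule(0:29999, tc), lr_sim)
  expect_true(all(diff(lr_schedule(0:29999, tc)) <= 0))
})

test_that("sparsification never touches the primary channel", {
  arr <- array(1, c(3, 3, 3, 4))
  expect_identical(sparsify_channels(arr, p = 0, draws = c(F, F, F)), arr)
  all_zeroed <- sparsify_channels(arr, p = 1, draws = c(T, T, T))
  expect_identical(all_zeroed[, , , 1], arr[, , , 1])
  for (i in 2:4) expect_true(all(all_zeroed[, , , i] == 0))
  # idempotent on already-zero channels
  expect_identical(sparsify_channels(all_zeroed, 1, draws = c(T, T, T)),
                   all_zeroed)
  # paired stacks share one draw
  pt <- list(high = array(1, c(2, 2, 2, 4)), low = array(1, c(2, 2, 2, 4)))
  set.seed(1)
  out <- sparsify_channels(pt, p = 0.5)
  zh <- vapply(2:4, function(i) all(out$high[, , , i] == 0), logical(1))
  zl <- vapply(2:4, function(i) all(out$low[, , , i] == 0), logical(1))
  expect_identical(zh, zl)
})

test_that("per-channel zeroing frequency matches the configured rate", {
  set.seed(2024)
  n <- 10000
  arr <- array(1, c(1, 1, 1, 4))
  hits <- matrix(0, n, 3)
  primary_intact <- TRUE
  for (i in seq_len(n)) {
    out <- sparsify_channels(arr, p = 0.2)
    hits[i, ] <- vapply(2:4, function(k) all(out[, , , k] == 0),
                        logical(1))
    primary_intact <- primary_intact && all(out[, , , 1] == 1)
  }
  expect_true(primary_intact)
  freq <- colMeans(hits)
  expect_true(all(freq >= 0.188 & freq <= 0.212))
})

test_that("soft Dice loss matches hand-computed values", {
  y <- c(1, 0)
  p <- c(0.5, 0.5)
  eps <- 1e-5
  expect_equal(dice_loss(p, y, eps = eps), 1 - (1 + eps) / (2 + eps))
  yy <- array(rep(c(0, 1), 8), c(2, 2, 4))
  expect_lt(dice_loss(yy, yy), 1e-4)
  expect_gt(dice_loss(1 - yy, yy), 1 - 1e-3)
})

test_that("patch sampling honors the two-pathway geometry", {
  cfg <- net_config("tiny")
  s <- make_subject(dims = c(30L, 30L, 30L), seed = 30)
  centroid <- round(colMeans(which(s$mask == 1, arr.ind = TRUE)))
  pt <- sparseseg:::patch_at(s, as.integer(centroid), cfg)
  expect_equal(dim(pt$high), c(15, 15, 15, 4))
  expect_equal(dim(pt$low), c(9, 9, 9, 4))
  expect_equal(dim(pt$label), c(9, 9, 9))
  # the mask cube is 5^3 around the centroid: label center must be 1
  expect_equal(pt$label[5, 5, 5], 1)
  # mean pooling of a constant volume is constant
  const <- array(2.5, c(9, 9, 9, 1))
  expect_true(all(sparseseg:::mean_pool3(const, 3) == 2.5))
  # out-of-volume context is zero-padded
  pt2 <- sparseseg:::patch_at(s, c(1L, 1L, 1L), cfg)
  expect_equal(pt2$high[1, 1, 1, 1], 0)
})

test_that("network construction is deterministic and numerically sane", {
  cfg <- net_config("tiny")
  n1 <- build_network(cfg, seed = 3)
  n2 <- build_network(cfg, seed = 3)
  expect_identical(n1$params, n2$params)
  expect_identical(n1$n_params, n2$n_params)
  n3 <- build_network(cfg, seed = 4)
  expect_false(identical(n1$params, n3$params))
  # forward pass on all-zero input yields finite logits
  zh <- array(0, c(rep(cfg$high_in, 3), 4))
  zl <- array(0, c(rep(cfg$low_in, 3), 4))
  fwd <- sparseseg:::net_forward(n1$params, cfg, zh, zl)
  expect_true(all(is.finite(fwd$logits)))
  expect_equal(nrow(fwd$prob), cfg$output_patch^3)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- net_config("tiny", feature_maps = c(3L, 3L, 4L), fc_layers = 5L)
  params <- build_network(cfg, seed = 7)$params
  set.seed(9)
  high <- array(stats::rnorm(cfg$high_in^3 * 4), c(rep(cfg$high_in, 3), 4))
  low <- array(stats::rnorm(cfg$low_in^3 * 4), c(rep(cfg$low_in, 3), 4))
  label <- array(stats::rbinom(cfg$output_patch^3, 1, 0.3),
                 rep(cfg$output_patch, 3))
  lossfun <- function(p) {
    fwd <- sparseseg:::net_forward(p, cfg, high, low)
    dice_loss(fwd$prob[, 2], label)
  }
  fwd <- sparseseg:::net_forward(params, cfg, high, low, want_cache = TRUE)
  dlog <- sparseseg:::dice_loss_grad_logits(fwd$prob, label)
  gr <- sparseseg:::net_backward(params, cfg, fwd, dlog)
  eps <- 1e-6
  for (k in c("high1.W", "low2.W", "high3.b", "fc1.W", "cls.W", "cls.b")) {
    i <- sample(length(params[[k]]), 1)
    p2 <- params
    p2[[k]][i] <- p2[[k]][i] + eps
    lp <- lossfun(p2)
    p2[[k]][i] <- p2[[k]][i] - 2 * eps
    lm <- lossfun(p2)
    num <- (lp - lm) / (2 * eps)
    expect_equal(gr[[k]][i], num, tolerance = 1e-4)
  }
})

test_that("batched forward equals per-sample forward", {
  cfg <- net_config("tiny", feature_maps = c(4L, 4L, 6L), fc_layers = 8L)
  params <- build_network(cfg, seed = 12)$params
  set.seed(13)
  pts <- lapply(1:3, function(i) list(
    high = array(stats::rnorm(cfg$high_in^3 * 4), c(rep(cfg$high_in, 3), 4)),
    low = array(stats::rnorm(cfg$low_in^3 * 4), c(rep(cfg$low_in, 3), 4))))
  fb <- sparseseg:::net_forward_batch(
    params, cfg,
    sparseseg:::bt_stack(lapply(pts, `[[`, "high")),
    sparseseg:::bt_stack(lapply(pts, `[[`, "low")), 3L)
  onpos <- cfg$output_patch^3
  for (b in 1:3) {
    f1 <- sparseseg:::net_forward(params, cfg, pts[[b]]$high, pts[[b]]$low)
    expect_equal(fb$prob[(b - 1) * onpos + seq_len(onpos), ], f1$prob,
                 tolerance = 1e-12)
  }
})
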