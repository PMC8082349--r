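# Fixture builders shared across test files.  Everything is generated
# in code under fixed seeds; nothing is read from disk.

random_mask <- function(dims, p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rbinom(prod(dims), 1, p), dims)
}

# A small complete-imaging phantom configuration that keeps the tumor
# placeable in a reduced volume.
small_phantom_config <- function(shape = 32L, seed = 1L, ...) {
  phantom_config(shape = shape, tumor_radius_range = c(4, 6),
                 seed = seed, ...)
}

# Hand-built subject on a tiny grid with controllable channel content.
make_subject <- function(dims = c(20L, 20L, 20L), seed = 1L,
                         missing = character(0), with_mask = TRUE) {
  set.seed(seed)
  brain <- array(0, dims)
  ctr <- (dims + 1) / 2
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    brain[i, j, ] <- as.numeric(
      ((i - ctr[1])^2 + (j - ctr[2])^2) <= (0.45 * dims[1])^2)
  # keep an axial slab so every z-slice has support
  channels <- lapply(channel_names(), function(ch)
    array(stats::runif(prod(dims), 0.2, 1), dims) * brain)
  names(channels) <- channel_names()
  available <- c(T1c = TRUE, T1w = TRUE, T2w = TRUE, FLAIR = TRUE)
  for (ch in missing) {
    channels[[ch]] <- array(0, dims)
    available[[ch]] <- FALSE
  }
  mask <- NULL
  if (with_mask) {
    mask <- array(0, dims)
    sel <- ctr[1] + (-2:2)
    mask[sel, sel, sel] <- 1
    mask <- mask * brain
  }
  mri_subject("test-subject", channels, available, c(1, 1, 1),
              brain_mask = brain, mask = mask)
}

# Independent brute-force metric oracles (kept deliberately naive and
# separate from the package implementation).
oracle_counts <- function(m, a) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(m)) {
    if (m[i] == 1 && a[i] == 1) tp <- tp + 1
    if (m[i] == 0 && a[i] == 1) fp <- fp + 1
    if (m[i] == 1 && a[i] == 0) fn <- fn + 1
  }
  list(tp = tp, fp = fp, fn = fn)
}

oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else 0,
      if (i < d[1]) mask[i + 1, j, k] else 0,
      if (j > 1) mask[i, j - 1, k] else 0,
      if (j < d[2]) mask[i, j + 1, k] else 0,
      if (k > 1) mask[i, j, k - 1] else 0,
      if (k < d[3]) mask[i, j, k + 1] else 0)
    if (any(nb == 0) || i == 1 || i == d[1] || j == 1 || j == d[2] ||
        k == 1 || k == d[3])
      out[i, j, k] <- TRUE
  }
  out
}

# Percentile by explicit linear interpolation between order statistics.
oracle_percentile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_hd95 <- function(m, a, spacing) {
  Pm <- which(oracle_boundary(m), arr.ind = TRUE)
  Pa <- which(oracle_boundary(a), arr.ind = TRUE)
  Pm <- sweep(Pm, 2, spacing, "*")
  Pa <- sweep(Pa, 2, spacing, "*")
  dmin <- function(A, B) {
    vapply(seq_len(nrow(A)), function(i) {
      sqrt(min(rowSums(sweep(B, 2, A[i, ], "-")^2)))
    }, numeric(1))
  }
  max(oracle_percentile(dmin(Pa, Pm), 0.95),
      oracle_percentile(dmin(Pm, Pa), 0.95))
}

# Exact two-sided signed-rank p-value by enumerating all sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
}
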