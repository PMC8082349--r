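test_that("generation is deterministic in (config, seed)", {
  cfg <- small_phantom_config()
  a <- generate_subject(cfg, 42)
  b <- generate_subject(cfg, 42)
  expect_identical(a$channels, b$channels)
  expect_identical(a$mask, b$mask)
  expect_identical(a$available, b$available)
  c <- generate_subject(cfg, 43)
  expect_false(identical(a$channels$T1c, c$channels$T1c))
})

test_that("mask volume matches the analytic blob volume up to a voxel shell", {
  cfg <- phantom_config(seed = 2)
  for (seed in c(5, 6, 7)) {
    s <- generate_subject(cfg, seed, force_complete = TRUE)
    vox_vol <- sum(s$mask) * prod(s$spacing)
    truth <- attr(s, "phantom_truth")$core_volume_mm3
    shell <- sum(sparseseg:::boundary_voxels(s$mask)) * prod(s$spacing)
    expect_lt(abs(vox_vol - truth), shell)
  }
})

test_that("tumor core is one 6-connected component inside the brain", {
  cfg <- phantom_config(seed = 3)
  s <- generate_subject(cfg, 11, force_complete = TRUE)
  expect_true(all(s$mask <= s$brain_mask))
  # flood fill from one core voxel
  idx <- which(s$mask == 1)
  d <- dim(s$mask)
  visited <- array(FALSE, d)
  start <- arrayInd(idx[1], d)
  queue <- list(as.integer(start))
  visited[idx[1]] <- TRUE
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    v <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (r in 1:6) {
      w <- v + nb[r, ]
      if (any(w < 1) || any(w > d)) next
      if (s$mask[w[1], w[2], w[3]] == 1 && !visited[w[1], w[2], w[3]]) {
        visited[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
  }
  expect_equal(sum(visited), length(idx))
})

test_that("noise-free contrast ordering matches the appearance model", {
  cfg <- phantom_config(noise_sd = 0, bias_amplitude = 0, seed = 4)
  s <- generate_subject(cfg, 21, force_complete = TRUE)
  truth <- attr(s, "phantom_truth")
  core <- s$mask == 1
  tissue <- s$brain_mask == 1 & s$mask == 0 & truth$halo == 0
  expect_gt(min(s$channels$FLAIR[core]), max(s$channels$FLAIR[tissue]))
  expect_lt(max(s$channels$T1w[core]), min(s$channels$T1w[tissue]))
  expect_gt(min(s$channels$T2w[core]), max(s$channels$T2w[tissue]))
  # a fixed threshold on the clean T1c recovers the enhancing rim exactly
  rim_rec <- (s$channels$T1c > 0.53) * 1
  expect_identical(rim_rec, truth$rim)
})

test_that("missingness frequency matches the configured fraction", {
  cfg <- phantom_config(shape = 16L, tumor_radius_range = c(2.5, 3.5),
                        missing_fraction = 0.5, seed = 5)
  n <- 200
  n_missing <- 0
  for (i in seq_len(n)) {
    s <- generate_subject(cfg, 3000 + i)
    if (!all(unlist(s$available))) n_missing <- n_missing + 1
  }
  # 95% binomial interval around 0.5 at n = 200
  expect_gte(n_missing / n, 0.5 - 1.96 * sqrt(0.25 / n))
  expect_lte(n_missing / n, 0.5 + 1.96 * sqrt(0.25 / n))

  cfg0 <- phantom_config(shape = 16L, tumor_radius_range = c(2.5, 3.5),
                         missing_fraction = 0, seed = 6)
  all_avail <- vapply(1:20, function(i)
    all(unlist(generate_subject(cfg0, i)$available)), logical(1))
  expect_true(all(all_avail))
})

test_that("cohorts are written reproducibly with the requested splits", {
  cfg <- small_phantom_config(seed = 9)
  d1 <- file.path(tempdir(), "cohA")
  d2 <- file.path(tempdir(), "cohB")
  m1 <- generate_cohort(cfg, 3, 1, 2, d1)
  m2 <- generate_cohort(cfg, 3, 1, 2, d2)
  expect_equal(nrow(m1), 6)
  expect_equal(length(unique(m1$subject_id)), 6)
  expect_equal(table(m1$split)[c("train", "val", "test")],
               table(c(rep("train", 3), "val", rep("test", 2)))[
                 c("train", "val", "test")])
  expect_identical(m1$T1c, m2$T1c)
  # identical bytes for a sample volume and the manifest body
  f1 <- file.path(d1, m1$T1c[1]); f2 <- file.path(d2, m2$T1c[1])
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # complete_test: every test subject has all four channels
  test_rows <- m1[m1$split == "test", ]
  expect_true(all(nzchar(as.matrix(test_rows[, channel_names()]))))
  # manifest round trip through the reader
  man <- read_manifest(file.path(d1, "manifest.csv"))
  subj <- read_split(man, "test")
  expect_length(subj, 2)
  expect_true(all(vapply(subj, function(s) !is.null(s$mask), logical(1))))
  unlink(c(d1, d2), recursive = TRUE)
})
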