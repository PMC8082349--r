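# Training-loop behavior on small phantom cohorts.  These runs use the
# tiny preset with few iterations: they check trends and contracts, not
# segmentation quality (the acceptance suite covers that).

make_train_cohort <- function(n, seed = 50L) {
  cfg <- small_phantom_config(seed = seed)
  lapply(seq_len(n), function(i)
    generate_subject(cfg, seed * 100 + i, force_complete = TRUE))
}

test_that("the loss trends downward during a short smoke run", {
  subjects <- make_train_cohort(4)
  tc <- train_config("tiny", iterations = 120L, batch_size = 8L, seed = 1L)
  m <- sparseseg(subjects, net_config("tiny"), tc, sparsified = FALSE)
  expect_s3_class(m, "sparseseg")
  expect_equal(nrow(m$log), 120L)
  expect_lt(stats::median(utils::tail(m$log$loss, 50)),
            stats::median(utils::head(m$log$loss, 50)))
  expect_true(all(is.finite(m$log$loss)))
})

test_that("training is bit-reproducible and p = 0 equals sparsified off", {
  subjects <- make_train_cohort(2, seed = 60L)
  nc <- net_config("tiny")
  tc <- train_config("tiny", iterations = 25L, batch_size = 4L, seed = 9L)
  m1 <- sparseseg(subjects, nc, tc, sparsified = FALSE)
  m2 <- sparseseg(subjects, nc, tc, sparsified = FALSE)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  # sparsified with p = 0 draws from a separate stream, so the patch
  # sequence and the result are identical to the plain run
  tc0 <- train_config("tiny", iterations = 25L, batch_size = 4L,
                      seed = 9L, sparsify_p = 0)
  m3 <- sparseseg(subjects, nc, tc0, sparsified = TRUE)
  expect_identical(m1$params, m3$params)
  expect_identical(m1$log, m3$log)
})

test_that("prediction is equivariant to shifts by one full stride", {
  cfg <- net_config("tiny")
  params <- build_network(cfg, seed = 77)$params
  model <- structure(list(params = params, net_cfg = cfg,
                          hist_model = NULL),
                     class = "sparseseg")
  dims <- c(45L, 45L, 45L)
  set.seed(5)
  content <- array(stats::rnorm(18 * 27 * 27), c(18, 27, 27))
  build <- function(x0) {
    ch <- lapply(channel_names(), function(i) {
      a <- array(0, dims)
      a[x0:(x0 + 17), 10:36, 10:36] <- content
      a
    })
    names(ch) <- channel_names()
    brain <- array(0, dims)
    brain[x0:(x0 + 17), 10:36, 10:36] <- 1
    s <- mri_subject("shift", ch,
                     c(T1c = TRUE, T1w = TRUE, T2w = TRUE, FLAIR = TRUE),
                     c(1, 1, 1), brain_mask = brain)
    attr(s, "normalized") <- TRUE
    s
  }
  p1 <- predict(model, build(10L), type = "prob",
                restrict_to_brain = FALSE)
  p2 <- predict(model, build(19L), type = "prob",
                restrict_to_brain = FALSE)
  expect_equal(p1[1:36, , ], p2[10:45, , ], tolerance = 1e-12)
})

test_that("pattern evaluation produces one row per subject and pattern", {
  subjects <- make_train_cohort(2, seed = 70L)
  hm <- fit_histogram_model(subjects)
  model <- structure(list(params = build_network(net_config("tiny"),
                                                 seed = 5)$params,
                          net_cfg = net_config("tiny"),
                          hist_model = hm),
                     class = "sparseseg")
  tab <- evaluate_model_under_patterns(model, subjects, model_id = "rnd")
  expect_equal(nrow(tab), 2L * 8L)
  expect_setequal(unique(tab$missing_pattern), names(missing_patterns()))
  expect_false(any(tab$confounded))
  # the empty pattern row equals plain predict-then-evaluate
  s1 <- subjects[[1]]
  pred <- predict(model, normalize_subject(s1, hm))
  ref <- evaluate_pair(seg_mask(s1$mask, s1$spacing), pred, s1$spacing)
  row <- tab[tab$subject_id == s1$subject_id &
               tab$missing_pattern == "none", ]
  expect_equal(row$dice, ref$dice)
  expect_equal(row$tp, ref$tp)
})

test_that("zeroed channels stay exactly zero through the whole chain", {
  cfg <- small_phantom_config(seed = 80L)
  dir <- file.path(tempdir(), "chain")
  generate_cohort(cfg, 2, 1, 1, dir, complete_test = TRUE)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  subjects <- read_split(man, "train")
  hm <- fit_histogram_model(subjects)
  s <- read_split(man, "test")[[1]]
  sp <- apply_missing_pattern(s, c("T2w", "FLAIR"))
  sn <- normalize_subject(sp, hm)
  expect_identical(max(abs(sn$channels$T2w)), 0)
  expect_identical(max(abs(sn$channels$FLAIR)), 0)
  # and in the sampled patch stacks
  pt <- sparseseg:::patch_at(sn, c(16L, 16L, 16L), net_config("tiny"))
  expect_true(all(pt$high[, , , 3:4] == 0))
  expect_true(all(pt$low[, , , 3:4] == 0))
  unlink(dir, recursive = TRUE)
})

test_that("model checkpoints survive a JSON round trip", {
  subjects <- make_train_cohort(2, seed = 90L)
  tc <- train_config("tiny", iterations = 5L, batch_size = 2L, seed = 2L)
  m <- sparseseg(subjects, net_config("tiny"), tc, sparsified = TRUE)
  path <- tempfile(fileext = ".json")
  save_sparseseg(m, path)
  back <- load_sparseseg(path)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  expect_identical(back$sparsified, TRUE)
  expect_equal(back$hist_model$landmarks, m$hist_model$landmarks)
  s <- subjects[[1]]
  expect_equal(predict(back, s)$voxels, predict(m, s)$voxels)
  unlink(path)
})
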