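test_that("pattern enumeration yields the 8 canonical subsets", {
  pats <- missing_patterns()
  expect_length(pats, 8L)
  expect_true("none" %in% names(pats))
  expect_equal(pats$none, character(0))
  expect_false(any(vapply(pats, function(p) "T1c" %in% p, logical(1))))
  expect_equal(unname(sort(lengths(pats))), c(0, 1, 1, 1, 2, 2, 2, 3))
})

test_that("apply_missing_pattern zeroes exactly the listed channels", {
  s <- make_subject(seed = 3)
  s2 <- apply_missing_pattern(s, c("T2w", "FLAIR"))
  expect_true(all(s2$channels$T2w == 0))
  expect_true(all(s2$channels$FLAIR == 0))
  expect_identical(s2$channels$T1c, s$channels$T1c)
  expect_identical(s2$channels$T1w, s$channels$T1w)
  expect_false(s2$available[["T2w"]])
  expect_false(s2$available[["FLAIR"]])
  # empty pattern is the identity; application is idempotent
  expect_identical(apply_missing_pattern(s, character(0)), s)
  expect_identical(apply_missing_pattern(s2, c("T2w", "FLAIR")), s2)
  # the input subject is untouched
  expect_gt(max(abs(s$channels$FLAIR)), 0)
  expect_error(apply_missing_pattern(s, "T1c"), "primary")
  expect_error(apply_missing_pattern(s, "B0"), "unknown")
})

test_that("wilcoxon signed-rank matches exact enumeration on small n", {
  # five strictly positive differences: p = 2/32
  r <- wilcoxon_signed_rank(c(1.1, 2.2, 3.3, 4.4, 5.5), c(1, 2, 3, 4, 5))
  expect_equal(r$p, 0.0625)
  expect_identical(r$method, "exact")
  # identical vectors are flagged, p = 1
  r0 <- wilcoxon_signed_rank(1:6, 1:6)
  expect_equal(r0$p, 1)
  expect_identical(r0$flag, "all_zero")

  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    d <- round(stats::rnorm(n), 3)
    while (anyDuplicated(abs(d)) || any(d == 0))
      d <- round(stats::rnorm(n), 3)
    a <- d / 2; b <- -d / 2                 # a - b == d exactly
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p, oracle_signed_rank_p(d), tolerance = 1e-12)
    # cross-check against the reference implementation
    expect_equal(got$p, stats::wilcox.test(a, b, paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon normal approximation tracks the reference for larger n", {
  set.seed(7)
  for (i in 1:10) {
    n <- 45                                 # beyond the exact-path limit
    d <- round(stats::rnorm(n, sd = 0.3), 1)
    d <- d[d != 0]
    a <- d / 2; b <- -d / 2
    got <- wilcoxon_signed_rank(a, b)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value)
    expect_equal(got$p, ref, tolerance = 1e-10)
  }
})

test_that("bonferroni adjustment is multiply-and-cap and monotone", {
  expect_equal(bonferroni_adjust(0.01, 72), 0.72)
  expect_equal(bonferroni_adjust(0.02, 72), 1)
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  set.seed(11)
  p <- stats::runif(50)
  adj <- bonferroni_adjust(p, 50)
  expect_equal(adj, pmin(1, p * 50))
  expect_equal(adj, stats::p.adjust(p, method = "bonferroni"))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= 0))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "lie in")
})

test_that("model comparison enforces pairing integrity by subject id", {
  tab <- data.frame(subject_id = rep(c("s1", "s2", "s3", "s4", "s5"), 2),
                    model_id = rep(c("a", "b"), each = 5),
                    missing_pattern = "none",
                    dice = c(0.9, 0.8, 0.7, 0.85, 0.95,
                             0.5, 0.42, 0.33, 0.44, 0.56))
  cmp <- compare_models(tab[tab$model_id == "a", ],
                        tab[tab$model_id == "b", ])
  expect_equal(cmp$n, 5)
  expect_equal(cmp$p_raw, 0.0625)     # all five differences positive
  expect_equal(cmp$median_diff, 0.39)
  bad <- tab[tab$model_id == "b", ]
  bad$subject_id <- paste0("x", bad$subject_id)
  expect_error(compare_models(tab[tab$model_id == "a", ], bad),
               "pairing integrity")
})
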