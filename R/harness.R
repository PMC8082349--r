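# Experimental harness: exhaustive missing-sequence simulation at
# inference, seed-matched model comparisons, paired Wilcoxon signed-rank
# tests with a single-family Bonferroni correction, and the end-to-end
# experiment driver.

#' All missing-sequence patterns
#'
#' The 2^3 = 8 subsets of the secondary channels (including the empty
#' pattern, named "none"), in a fixed canonical order.
#'
#' @return Named list of character vectors of channel names.
#' @export
missing_patterns <- function() {
  sec <- secondary_channels()
  pats <- list()
  for (k in 0:length(sec)) {
    combs <- utils::combn(sec, k, simplify = FALSE)
    for (cb in combs) {
      nm <- if (length(cb) == 0) "none" else paste(cb, collapse = "+")
      pats[[nm]] <- cb
    }
  }
  pats
}

#' Simulate missing sequences on a subject
#'
#' The listed secondary channels are zero-filled and flagged
#' unavailable; all other data are untouched and the input subject is
#' not modified.  Works on raw or normalized subjects (zeros survive
#' normalization by the zero-preservation invariant).  Idempotent.
#'
#' @param subject An \code{\link{mri_subject}}.
#' @param pattern Character vector of secondary channel names (possibly
#'   empty), or a pattern name like "T2w+FLAIR" / "none".
#' @return The modified copy of the subject.
#' @export
apply_missing_pattern <- function(subject, pattern) {
  if (is.character(pattern) && length(pattern) == 1L &&
      (pattern == "none" || grepl("+", pattern, fixed = TRUE)))
    pattern <- pattern_to_channels(pattern)
  bad <- setdiff(pattern, secondary_channels())
  if (length(bad))
    stop("pattern names unknown or primary channels: ",
         paste(bad, collapse = ", "))
  out <- subject
  dims <- dim(subject$channels[[1]])
  for (ch in pattern) {
    out$channels[[ch]] <- array(0, dim = dims)
    out$available[[ch]] <- FALSE
  }
  out
}

#' Evaluate a model on test subjects under all missing patterns
#'
#' Each subject is normalized once with the model's histogram model,
#' then every pattern is applied and segmented, giving one metric row
#' per (subject, pattern).  Patterns that cannot be realized cleanly
#' because the subject originally lacks a channel outside the pattern
#' are flagged \code{confounded}.
#'
#' @param model A fitted \code{\link{sparseseg}} model.
#' @param subjects Test subjects with ground-truth masks.
#' @param patterns Patterns as from \code{\link{missing_patterns}}.
#' @param model_id Identifier recorded in the output.
#' @return data.frame: subject_id, model_id, missing_pattern, metrics,
#'   confounded flag.
#' @export
evaluate_model_under_patterns <- function(model, subjects,
                                          patterns = missing_patterns(),
                                          model_id = "model") {
  rows <- list()
  for (s in subjects) {
    if (is.null(s$mask)) stop("subject ", s$subject_id, " has no mask")
    sn <- if (isTRUE(attr(s, "normalized"))) s
          else normalize_subject(s, model$hist_model)
    orig_missing <- secondary_channels()[
      !vapply(secondary_channels(), function(c) s$available[[c]],
              logical(1))]
    for (nm in names(patterns)) {
      pat <- patterns[[nm]]
      sp <- apply_missing_pattern(sn, pat)
      pred <- predict(model, sp)
      met <- evaluate_pair(seg_mask(s$mask, s$spacing), pred, s$spacing)
      met$subject_id <- s$subject_id
      met$model_id <- model_id
      met$missing_pattern <- nm
      met$confounded <- length(setdiff(orig_missing, pat)) > 0
      rows[[length(rows) + 1L]] <- met
    }
  }
  out <- do.call(rbind, rows)
  out[, c("subject_id", "model_id", "missing_pattern", "dice",
          "sensitivity", "hd95", "tp", "fp", "fn", "flags",
          "confounded")]
}

#' Paired Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped (classic Wilcoxon handling; Pratt's
#' method via \code{zero_method = "pratt"} keeps them in the ranking).
#' With at most 25 non-zero differences and no ties among their
#' absolute values the exact null distribution of the signed-rank
#' statistic is used; otherwise a normal approximation with continuity
#' and tie correction.
#'
#' @param a,b Equal-length numeric vectors of paired scores.
#' @param zero_method "wilcox" (drop zeros, default) or "pratt".
#' @return List with \code{p} (two-sided), \code{statistic} (W+),
#'   \code{n_used}, \code{n_zero}, \code{method} and \code{flag}.
#' @export
wilcoxon_signed_rank <- function(a, b, zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(a) == length(b))
  d <- a - b
  n_zero <- sum(d == 0)
  if (all(d == 0))
    return(list(p = 1, statistic = 0, n_used = 0L, n_zero = n_zero,
                method = "degenerate", flag = "all_zero"))
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
    n <- length(d)
    W <- sum(r[d > 0])
    ties <- anyDuplicated(r) > 0
    if (!ties && n <= 25L) {
      p <- 2 * min(stats::psignrank(W, n),
                   1 - stats::psignrank(W - 1, n))
      return(list(p = min(1, p), statistic = W, n_used = n,
                  n_zero = n_zero, method = "exact", flag = ""))
    }
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  } else {
    # Pratt: zeros keep their (low) ranks in the ranking but are then
    # discarded; null moments subtract the zero block.
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    n <- length(a)
    nz <- n_zero
    W <- sum(r[d[keep] > 0])
    ties <- anyDuplicated(r_all) > 0
    mu <- (n * (n + 1) - nz * (nz + 1)) / 4
    tab <- table(r_all)
    sigma2 <- (n * (n + 1) * (2 * n + 1) -
                 nz * (nz + 1) * (2 * nz + 1)) / 24 -
      sum(tab^3 - tab) / 48
    n <- sum(keep)
  }
  z_num <- W - mu
  z_num <- z_num - sign(z_num) * 0.5          # continuity correction
  z <- z_num / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(p = min(1, p), statistic = W, n_used = n, n_zero = n_zero,
       method = "normal", flag = if (ties) "ties" else "")
}

#' Single-family Bonferroni adjustment
#'
#' Each p-value is multiplied by the total number of tests in the
#' family and capped at 1.  The family size defaults to the length of
#' the input but can be set explicitly to the size of the full
#' comparison family of a run.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @param n_tests Family size (default \code{length(p_values)}).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, n_tests = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (n_tests < 1) stop("n_tests must be >= 1")
  pmin(1, p_values * n_tests)
}

#' Paired per-pattern comparison of two models
#'
#' Pairs the Dice scores of two models by subject within each missing
#' pattern (pairing integrity asserted on subject ids) and runs the
#' two-sided Wilcoxon signed-rank test.  Bonferroni adjustment is
#' applied by the caller over the full family.
#'
#' @param tab_a,tab_b Metric tables from
#'   \code{\link{evaluate_model_under_patterns}}.
#' @param metric Column to compare (default "dice").
#' @return data.frame with one row per pattern.
#' @export
compare_models <- function(tab_a, tab_b, metric = "dice") {
  pats <- unique(tab_a$missing_pattern)
  rows <- lapply(pats, function(nm) {
    ra <- tab_a[tab_a$missing_pattern == nm, ]
    rb <- tab_b[tab_b$missing_pattern == nm, ]
    ra <- ra[order(ra$subject_id), ]
    rb <- rb[order(rb$subject_id), ]
    if (!identical(ra$subject_id, rb$subject_id))
      stop("pairing integrity violated for pattern ", nm)
    wt <- wilcoxon_signed_rank(ra[[metric]], rb[[metric]])
    data.frame(model_a = ra$model_id[1], model_b = rb$model_id[1],
               pattern = nm, n = nrow(ra),
               median_a = stats::median(ra[[metric]]),
               median_b = stats::median(rb[[metric]]),
               median_diff = stats::median(ra[[metric]] - rb[[metric]]),
               p_raw = wt$p, statistic = wt$statistic,
               method = wt$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full desk-scale experiment
#'
#' Generates (or reuses) a phantom cohort, trains a seed-matched grid of
#' models with and without sparsified training, evaluates every model on
#' the complete-imaging test split under all 8 missing patterns, runs
#' the paired per-pattern Wilcoxon comparisons with a single Bonferroni
#' family over all computed p-values, and writes CSV tables plus a
#' per-pattern box-plot figure.  Models in the grid share the training
#' seed, so pairs differing only in sparsification have identical
#' initialization and patch sequences.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for cohort generation and training.
#' @param n_train,n_val,n_test Cohort split sizes.
#' @param phantom Optional \code{\link{phantom_config}} override (its
#'   seed is replaced by \code{seed}).
#' @param net_cfg,train_cfg Network / training configuration (the
#'   training seed is replaced by \code{seed}).
#' @param grid data.frame of model variants with columns \code{model_id},
#'   \code{sparsified}, \code{complete_only}; default the seed-matched
#'   \{plain, sparsified\} pair on all training data.
#' @param make_plot Write the per-pattern box-plot PNG (default TRUE).
#' @return Invisibly, a list with the metric table, the comparison
#'   table, family size, and output paths.
#' @export
run_experiment <- function(out_dir, seed = 1L,
                           n_train = 12L, n_val = 2L, n_test = 6L,
                           phantom = NULL,
                           net_cfg = net_config("tiny"),
                           train_cfg = train_config("tiny"),
                           grid = NULL,
                           make_plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(phantom)) phantom <- phantom_config(seed = seed)
  else phantom$seed <- as.integer(seed)
  train_cfg$seed <- as.integer(seed)
  if (is.null(grid))
    grid <- data.frame(model_id = c("plain", "sparsified"),
                       sparsified = c(FALSE, TRUE),
                       complete_only = FALSE,
                       stringsAsFactors = FALSE)

  cohort_dir <- file.path(out_dir, "cohort")
  man <- generate_cohort(phantom, n_train, n_val, n_test, cohort_dir)
  manifest <- read_manifest(attr(man, "path"))
  train_subj <- read_split(manifest, "train")
  test_subj <- read_split(manifest, "test")

  models <- list()
  for (i in seq_len(nrow(grid))) {
    subj <- train_subj
    if (grid$complete_only[i]) {
      subj <- Filter(function(s) all(unlist(s$available)), subj)
      if (!length(subj)) stop("no complete-imaging training subjects")
    }
    models[[grid$model_id[i]]] <-
      sparseseg(subj, net_cfg, train_cfg,
                sparsified = grid$sparsified[i])
  }

  metric_tab <- do.call(rbind, lapply(names(models), function(id)
    evaluate_model_under_patterns(models[[id]], test_subj,
                                  model_id = id)))
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(format_numeric_df(metric_tab), metrics_path,
                   row.names = FALSE)

  # one comparison per (sparsified, plain) counterpart pair per pattern;
  # single Bonferroni family over all raw p-values of the run
  comp <- NULL
  for (i in seq_len(nrow(grid))) {
    if (!grid$sparsified[i]) next
    mate <- which(!grid$sparsified &
                    grid$complete_only == grid$complete_only[i])
    if (!length(mate)) next
    id_a <- grid$model_id[i]
    id_b <- grid$model_id[mate[1]]
    cmp <- compare_models(metric_tab[metric_tab$model_id == id_a, ],
                          metric_tab[metric_tab$model_id == id_b, ])
    comp <- rbind(comp, cmp)
  }
  if (!is.null(comp)) {
    comp$n_tests <- nrow(comp)
    comp$p_adjusted <- bonferroni_adjust(comp$p_raw, nrow(comp))
    comp$significant <- comp$p_adjusted < 0.05
  }
  comparisons_path <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(format_numeric_df(comp), comparisons_path,
                   row.names = FALSE)

  plot_path <- file.path(out_dir, "dice_by_pattern.png")
  if (make_plot) {
    grDevices::png(plot_path, width = 1400, height = 700, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_dice_by_pattern(metric_tab)
  }

  training_log_path <- file.path(out_dir, "training_log.csv")
  logs <- do.call(rbind, lapply(names(models), function(id) {
    lg <- models[[id]]$log
    lg$model_id <- id
    lg
  }))
  utils::write.csv(format_numeric_df(logs), training_log_path,
                   row.names = FALSE)

  invisible(list(models = models, metrics = metric_tab,
                 comparisons = comp,
                 n_tests = if (is.null(comp)) 0L else nrow(comp),
                 paths = list(metrics = metrics_path,
                              comparisons = comparisons_path,
                              plot = if (make_plot) plot_path else NULL,
                              training_log = training_log_path,
                              manifest = attr(man, "path"))))
}

# Fixed-precision formatting so output CSVs are byte-stable across runs
# and platforms.
format_numeric_df <- function(df) {
  if (is.null(df)) return(data.frame())
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- formatC(df[[col]], format = "g", digits = 10)
  }
  df
}

#' Box plots of Dice by missing pattern and model
#'
#' Mirrors the layout of a per-pattern model comparison: one group of
#' boxes per missing pattern, one box per model.
#'
#' @param metric_tab Table from
#'   \code{\link{evaluate_model_under_patterns}} (possibly several
#'   models row-bound).
#' @export
plot_dice_by_pattern <- function(metric_tab) {
  pats <- names(missing_patterns())
  pats <- pats[pats %in% unique(metric_tab$missing_pattern)]
  models <- unique(metric_tab$model_id)
  metric_tab$missing_pattern <- factor(metric_tab$missing_pattern,
                                       levels = pats)
  metric_tab$model_id <- factor(metric_tab$model_id, levels = models)
  cols <- grDevices::hcl.colors(max(2L, length(models)), "Dark 2")
  graphics::boxplot(dice ~ model_id + missing_pattern, data = metric_tab,
                    col = cols[seq_along(models)],
                    las = 2, xlab = "", ylab = "Dice",
                    main = "Dice by simulated missing pattern",
                    cex.axis = 0.7)
  graphics::legend("bottomleft", legend = models,
                   fill = cols[seq_along(models)], bty = "n")
  invisible(NULL)
}
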