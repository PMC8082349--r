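# Histogram normalization (percentile-landmark mapping) followed by
# whitening to zero mean / unit variance over the brain support, with the
# missing-channel adjustment: channels flagged unavailable pass through
# exactly unchanged, so an all-zero (missing) channel enters the network
# at the whitened mean of the available data.

LANDMARK_PCT <- c(1, seq(10, 90, by = 10), 99) / 100

#' Fit a percentile-landmark histogram model
#'
#' For each channel, foreground intensities (inside \code{brain_mask})
#' are pooled over all training subjects in which the channel is
#' available, and landmark percentiles at \{1, 10, 20, ..., 90, 99\} are
#' recorded as that channel's standard scale.  Channels flagged missing
#' never contribute.  Pooling is order-independent, so the model is
#' deterministic in the subject set.
#'
#' @param subjects List of \code{\link{mri_subject}} objects.
#' @return An object of class \code{histogram_model}.
#' @export
fit_histogram_model <- function(subjects) {
  if (length(subjects) < 1L) stop("need at least one subject")
  landmarks <- list()
  for (ch in channel_names()) {
    pool <- numeric(0)
    for (s in subjects) {
      if (s$available[[ch]])
        pool <- c(pool, s$channels[[ch]][s$brain_mask == 1])
    }
    if (!length(pool))
      stop("channel ", ch, " is available in no subject; ",
           "cannot fit its landmarks")
    lm <- as.numeric(stats::quantile(pool, LANDMARK_PCT, type = 7,
                                     names = FALSE))
    if (any(diff(lm) <= 0))
      stop("degenerate intensity distribution for channel ", ch,
           ": landmark percentiles are not strictly increasing ",
           "(constant or near-constant foreground)")
    landmarks[[ch]] <- lm
  }
  structure(list(percentiles = LANDMARK_PCT, landmarks = landmarks),
            class = "histogram_model")
}

#' @export
print.histogram_model <- function(x, ...) {
  cat("<histogram_model> landmarks at {",
      paste(x$percentiles * 100, collapse = ", "), "}%\n")
  for (ch in names(x$landmarks))
    cat(sprintf("  %-5s [%.3g .. %.3g]\n", ch,
                min(x$landmarks[[ch]]), max(x$landmarks[[ch]])))
  invisible(x)
}

#' Normalize a subject against a histogram model
#'
#' Available channels get the piecewise-linear landmark mapping onto the
#' model's standard scale (linear extrapolation beyond the outer
#' landmarks), then whitening to mean 0 / SD 1 computed over the brain
#' mask and applied to the whole volume.  Channels flagged unavailable
#' are returned exactly as-is (identically zero), never remapped: a
#' missing channel must reach the network indistinguishable from a
#' channel zeroed by the sparsification layer.
#'
#' Missing-channel detection uses the \code{available} flag only, never
#' an intensity heuristic, so a legitimately dark-but-present channel is
#' never misclassified.
#'
#' @param subject An \code{\link{mri_subject}}.
#' @param model A \code{\link{fit_histogram_model}} result.
#' @return The normalized subject (attribute \code{normalized} set).
#' @export
normalize_subject <- function(subject, model) {
  stopifnot(inherits(model, "histogram_model"))
  if (!identical(names(model$landmarks), channel_names()))
    stop("model channels do not match the subject's channels")
  fg <- subject$brain_mask == 1
  out <- subject
  for (ch in channel_names()) {
    if (!subject$available[[ch]]) next   # zero-preservation, bit-exact
    v <- subject$channels[[ch]]
    own <- as.numeric(stats::quantile(v[fg], model$percentiles, type = 7,
                                      names = FALSE))
    if (any(diff(own) <= 0))
      stop("degenerate intensity distribution in subject ",
           subject$subject_id, " channel ", ch)
    mapped <- piecewise_linear_map(as.numeric(v), own,
                                   model$landmarks[[ch]])
    m <- mean(mapped[fg])
    s <- stats::sd(mapped[fg])
    if (s <= 0) stop("zero variance after mapping for channel ", ch)
    out$channels[[ch]] <- array((mapped - m) / s, dim = dim(v))
  }
  attr(out, "normalized") <- TRUE
  out
}

# Monotone piecewise-linear map through (x_landmarks, y_landmarks) with
# linear extrapolation beyond the outer landmarks.
piecewise_linear_map <- function(v, x_lm, y_lm) {
  n <- length(x_lm)
  y <- stats::approx(x_lm, y_lm, xout = v, rule = 2)$y
  lo <- v < x_lm[1]
  if (any(lo)) {
    slope <- (y_lm[2] - y_lm[1]) / (x_lm[2] - x_lm[1])
    y[lo] <- y_lm[1] + (v[lo] - x_lm[1]) * slope
  }
  hi <- v > x_lm[n]
  if (any(hi)) {
    slope <- (y_lm[n] - y_lm[n - 1]) / (x_lm[n] - x_lm[n - 1])
    y[hi] <- y_lm[n] + (v[hi] - x_lm[n]) * slope
  }
  y
}

#' Serialize a histogram model to JSON
#' @param model A \code{histogram_model}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
save_histogram_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Load a histogram model from JSON
#' @param path JSON path written by \code{\link{save_histogram_model}}.
#' @return A \code{histogram_model}.
#' @export
load_histogram_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(percentiles = as.numeric(raw$percentiles),
                 landmarks = lapply(raw$landmarks, as.numeric)),
            class = "histogram_model")
}
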