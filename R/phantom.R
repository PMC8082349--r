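# Synthetic multi-channel phantom cohort.
#
# Each subject is an ellipsoidal "brain" on a dark background carrying a
# randomly deformed tumor-core blob (enhancing rim around an enclosed
# necrotic core).  The four channels render the same latent geometry with
# different, partially redundant contrasts, so the core is in principle
# recoverable from the primary channel alone while the FLAIR analog gives
# the easiest (whole-core bright) signal.  A smooth multiplicative bias
# field and additive Gaussian noise are applied per channel, and a
# configurable fraction of subjects has one or more secondary channels
# zero-filled.

#' Phantom generator configuration
#'
#' @param shape Per-axis voxel counts (default 48 isotropic).
#' @param spacing Voxel size in mm (default 1 mm isotropic).
#' @param noise_sd Additive Gaussian noise SD, in the same arbitrary
#'   intensity units as the tissue contrasts (tissue-to-core contrasts
#'   are 0.3-0.5 units; default 0.08).
#' @param bias_amplitude Half-range of the smooth multiplicative bias
#'   field (default 0.2, i.e. +/-20 percent).
#' @param tumor_radius_range Min/max mean blob radius in mm.
#' @param rim_width Enhancing-rim thickness in mm.
#' @param halo_width Peritumoral FLAIR-halo thickness in mm.
#' @param deform_amp Relative amplitude of the smooth radial deformation
#'   of the blob (0 = perfect sphere).
#' @param missing_fraction Probability that a subject has at least one
#'   missing secondary channel (default 0.5, matching a cohort in which
#'   roughly half the subjects have incomplete imaging).
#' @param missing_pattern_weights Named numeric over the 7 non-empty
#'   subsets of secondary channels (names like "T2w" or "T2w+FLAIR"),
#'   normalized internally.  The default makes a missing T2w the most
#'   common pattern and missing T2w+FLAIR the next.
#' @param seed Master seed for the cohort.
#' @return A list of class \code{phantom_config}.
#' @export
phantom_config <- function(shape = c(48L, 48L, 48L),
                           spacing = c(1, 1, 1),
                           noise_sd = 0.08,
                           bias_amplitude = 0.2,
                           tumor_radius_range = c(6, 10),
                           rim_width = 2,
                           halo_width = 3,
                           deform_amp = 0.25,
                           missing_fraction = 0.5,
                           missing_pattern_weights = NULL,
                           seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  if (any(shape < 16L)) stop("shape must be >= 16 voxels per axis")
  if (missing_fraction < 0 || missing_fraction > 1)
    stop("missing_fraction must lie in [0, 1]")
  if (is.null(missing_pattern_weights))
    missing_pattern_weights <- c(
      "T2w" = 0.40, "T2w+FLAIR" = 0.25, "FLAIR" = 0.10,
      "T1w" = 0.08, "T1w+T2w" = 0.07, "T1w+FLAIR" = 0.05,
      "T1w+T2w+FLAIR" = 0.05)
  w <- missing_pattern_weights
  if (any(w < 0) || sum(w) <= 0) stop("invalid pattern weights")
  for (nm in names(w)) {
    parts <- strsplit(nm, "+", fixed = TRUE)[[1]]
    if (!all(parts %in% secondary_channels()))
      stop("pattern weight names must be subsets of the secondary ",
           "channels joined by '+': bad name '", nm, "'")
  }
  w <- w / sum(w)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 tumor_radius_range = tumor_radius_range,
                 rim_width = rim_width, halo_width = halo_width,
                 deform_amp = deform_amp,
                 missing_fraction = missing_fraction,
                 missing_pattern_weights = w,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Trilinear interpolation of a control-point grid onto a regular grid
# given per-axis normalized coordinates in [0, 1].  Control values are
# scaled to [-1, 1] so the interpolated field is bounded independently
# of the evaluation grid.
eval_ctrl_field <- function(ctrl, u_list) {
  nc <- dim(ctrl)[1]
  ax <- lapply(u_list, function(u) {
    g <- u * (nc - 1) + 1
    i0 <- pmin(floor(g), nc - 1)
    list(i0 = as.integer(i0), w = g - i0)
  })
  dims <- vapply(u_list, length, integer(1))
  out <- array(0, dim = dims)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wx <- if (a) ax[[1]]$w else 1 - ax[[1]]$w
    wy <- if (b) ax[[2]]$w else 1 - ax[[2]]$w
    wz <- if (cc) ax[[3]]$w else 1 - ax[[3]]$w
    sub <- ctrl[ax[[1]]$i0 + a, ax[[2]]$i0 + b, ax[[3]]$i0 + cc,
                drop = FALSE]
    out <- out + outer(outer(wx, wy), wz) * array(sub, dims)
  }
  out
}

new_ctrl_grid <- function(n_ctrl = 4L) {
  v <- stats::rnorm(n_ctrl^3)
  v <- v / max(abs(v))
  array(v, dim = rep(n_ctrl, 3L))
}

unit_coords <- function(n) (seq_len(n) - 0.5) / n

# Squared mm distance of every grid point from a center (mm units).
grid_dist_mm <- function(shape, spacing, center_mm, u_list = NULL) {
  if (is.null(u_list)) u_list <- lapply(shape, unit_coords)
  axes_mm <- lapply(1:3, function(k) u_list[[k]] * shape[k] * spacing[k])
  dx2 <- (axes_mm[[1]] - center_mm[1])^2
  dy2 <- (axes_mm[[2]] - center_mm[2])^2
  dz2 <- (axes_mm[[3]] - center_mm[3])^2
  sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
}

pattern_to_channels <- function(name) {
  if (identical(name, "none") || !nzchar(name)) return(character(0))
  strsplit(name, "+", fixed = TRUE)[[1]]
}

#' Generate one phantom subject
#'
#' Deterministic given \code{(config, subject_seed)}.  The returned
#' subject carries a \code{phantom_truth} attribute with the generating
#' parameters and an oversampled (analytic) core volume in mm^3.
#'
#' @param config A \code{\link{phantom_config}}.
#' @param subject_seed Integer seed for this subject.
#' @param force_complete If TRUE, all four channels are generated
#'   regardless of the missingness settings.
#' @param subject_id Identifier (default derived from the seed).
#' @return An \code{\link{mri_subject}} with ground-truth mask.
#' @export
generate_subject <- function(config, subject_seed,
                             force_complete = FALSE,
                             subject_id = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(as.integer(subject_seed))
  if (is.null(subject_id)) subject_id <- sprintf("phantom-%d", subject_seed)
  shape <- config$shape
  spacing <- config$spacing
  extent_mm <- shape * spacing
  semi_mm <- 0.42 * extent_mm          # brain ellipsoid semi-axes
  center_mm <- extent_mm / 2

  u <- lapply(shape, unit_coords)
  axes_mm <- lapply(1:3, function(k) u[[k]] * extent_mm[k])
  en <- function(u_list) {             # ellipsoid norm (<1 inside brain)
    am <- lapply(1:3, function(k) u_list[[k]] * extent_mm[k])
    ex <- ((am[[1]] - center_mm[1]) / semi_mm[1])^2
    ey <- ((am[[2]] - center_mm[2]) / semi_mm[2])^2
    ez <- ((am[[3]] - center_mm[3]) / semi_mm[3])^2
    sqrt(outer(outer(ex, ey, "+"), ez, "+"))
  }
  brain <- (en(u) <= 1) * 1

  # Place the tumor blob fully inside the brain; bounded retries.
  r_rng <- config$tumor_radius_range
  placed <- FALSE
  for (attempt in seq_len(25L)) {
    r0 <- stats::runif(1, r_rng[1], r_rng[2])
    ctrl <- new_ctrl_grid(4L)
    # max blob radius in mm, used for the inside-brain placement margin
    r_max <- r0 * (1 + config$deform_amp) + config$halo_width
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    rad_frac <- stats::runif(1, 0, 0.55)
    cand <- center_mm + dir * rad_frac * (semi_mm - r_max)
    # candidate acceptable if the whole deformed blob stays inside
    margin_ok <- all(((cand - center_mm) / (semi_mm - r_max))^2 <= 1) &&
      all(semi_mm - r_max > 0)
    if (margin_ok) { placed <- TRUE; break }
  }
  if (!placed)
    stop("could not place tumor inside brain after bounded attempts; ",
         "reduce tumor_radius_range relative to the volume shape")

  dist_mm <- grid_dist_mm(shape, spacing, cand, u)
  g <- eval_ctrl_field(ctrl, u)
  r_local <- r0 * (1 + config$deform_amp * g)
  core <- (dist_mm <= r_local) * 1
  rim <- core * (dist_mm > (r_local - config$rim_width))
  necro <- core - rim
  halo <- (dist_mm <= r_local + config$halo_width) * brain * (1 - core)

  # Analytic core volume: same implicit function on a 2x oversampled grid.
  u2 <- lapply(2L * shape, unit_coords)
  dist2 <- grid_dist_mm(shape, spacing, cand, u2)
  g2 <- eval_ctrl_field(ctrl, u2)
  core_vol_mm3 <- sum(dist2 <= r0 * (1 + config$deform_amp * g2)) *
    prod(spacing) / 8

  # Appearance model (pre-bias, pre-noise), air = 0.
  paint <- function(tissue, core_val = NULL, rim_val = NULL,
                    necro_val = NULL, halo_val = NULL) {
    v <- brain * tissue
    if (!is.null(halo_val)) v <- v * (1 - halo) + halo * halo_val
    if (!is.null(core_val)) v <- v * (1 - core) + core * core_val
    if (!is.null(rim_val)) v <- v * (1 - rim) + rim * rim_val
    if (!is.null(necro_val)) v <- v * (1 - necro) + necro * necro_val
    v
  }
  # Channel contrasts: FLAIR carries the strongest, easiest core signal
  # (bright over the whole core plus a halo); the primary T1c shows a
  # subtler enhancing rim around a mildly hypointense necrotic core, and
  # T1w/T2w sit in between.  The core is recoverable from T1c alone, but
  # a network free to pick its features will lean on FLAIR first --
  # the cross-channel redundancy the sparsified protocol exploits.
  clean <- list(
    T1c   = paint(0.50, rim_val = 0.56, necro_val = 0.455),
    T1w   = paint(0.55, core_val = 0.51),
    T2w   = paint(0.40, core_val = 0.48),
    FLAIR = paint(0.42, core_val = 0.92, halo_val = 0.76))

  channels <- lapply(clean, function(v) {
    bias <- 1 + config$bias_amplitude * eval_ctrl_field(new_ctrl_grid(3L), u)
    v <- v * bias
    if (config$noise_sd > 0)
      v <- v + stats::rnorm(length(v), sd = config$noise_sd)
    array(v, dim = shape)
  })

  available <- c(T1c = TRUE, T1w = TRUE, T2w = TRUE, FLAIR = TRUE)
  if (!force_complete && config$missing_fraction > 0 &&
      stats::runif(1) < config$missing_fraction) {
    w <- config$missing_pattern_weights
    nm <- sample(names(w), 1L, prob = w)
    for (ch in pattern_to_channels(nm)) {
      channels[[ch]] <- array(0, dim = shape)
      available[[ch]] <- FALSE
    }
  }

  subj <- mri_subject(subject_id, channels, available, spacing,
                      brain_mask = brain, mask = core)
  attr(subj, "phantom_truth") <- list(
    center_mm = cand, r0 = r0, deform_amp = config$deform_amp,
    core_volume_mm3 = core_vol_mm3, clean = clean,
    rim = rim, necro = necro, halo = halo)
  subj
}

#' Generate a phantom cohort on disk
#'
#' Writes one NIfTI file per available channel plus tumor and brain
#' masks, and a manifest CSV readable by \code{\link{read_manifest}}.
#' All randomness flows from \code{config$seed} through per-subject
#' derived seeds, so two runs with the same configuration produce
#' identical manifests and file contents.
#'
#' @param config A \code{\link{phantom_config}}.
#' @param n_train,n_val,n_test Split sizes (each >= 1).
#' @param dir Output directory (created if needed).
#' @param complete_test If TRUE (default), test subjects are generated
#'   with complete imaging, mirroring a test set restricted to patients
#'   with all four sequences so every missing pattern can be simulated.
#' @return Invisibly, the manifest data.frame (with the manifest path in
#'   attribute \code{path}).
#' @export
generate_cohort <- function(config, n_train, n_val, n_test, dir,
                            complete_test = TRUE) {
  stopifnot(n_train >= 1, n_val >= 1, n_test >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  splits <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  rows <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sid <- sprintf("sub-%03d", i)
    seed_i <- derive_seed(config$seed, salt = 101L, i = i)
    subj <- generate_subject(
      config, seed_i, force_complete = complete_test && splits[i] == "test",
      subject_id = sid)
    row <- list(subject_id = sid, split = splits[i])
    for (ch in channel_names()) {
      if (subj$available[[ch]]) {
        fn <- sprintf("%s_%s.nii.gz", sid, ch)
        write_scalar_volume(subj$channels[[ch]], subj$spacing,
                            file.path(dir, fn))
        row[[ch]] <- fn
      } else row[[ch]] <- ""
    }
    fn_mask <- sprintf("%s_mask.nii.gz", sid)
    write_mask(seg_mask(subj$mask, subj$spacing), file.path(dir, fn_mask))
    row$mask <- fn_mask
    fn_brain <- sprintf("%s_brain.nii.gz", sid)
    write_mask(seg_mask(subj$brain_mask, subj$spacing),
               file.path(dir, fn_brain))
    row$brain_mask <- fn_brain
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  attr(man, "path") <- path
  invisible(man)
}
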