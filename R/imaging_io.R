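# NIfTI plumbing: subjects come in as one file per channel plus optional
# masks; absent secondary channels are materialized as zero-filled volumes
# on the primary channel's grid.  Volumes are used in the on-disk voxel
# lattice; no reorientation or resampling is performed (inputs are assumed
# co-registered and resampled upstream).

SPACING_RTOL <- 1e-4

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[seq_len(3)])
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  list(voxels = arr, spacing = nifti_spacing(img))
}

#' Read a subject from per-channel NIfTI files
#'
#' The primary channel (T1c) is required.  Secondary channels whose path
#' is \code{NA} or empty are treated as missing: they are zero-filled on
#' the common grid and flagged unavailable.  All provided files must
#' share the primary channel's grid exactly (shapes) and its spacing to
#' a relative tolerance of 1e-4.
#'
#' @param paths Named character vector or list with entries for
#'   \code{T1c}, \code{T1w}, \code{T2w}, \code{FLAIR} (secondary entries
#'   may be NA/empty), and optionally \code{mask} and \code{brain_mask}.
#' @param subject_id Identifier; defaults to the T1c filename stem.
#' @return An \code{\link{mri_subject}}.
#' @export
read_subject <- function(paths, subject_id = NULL) {
  paths <- as.list(paths)
  p_primary <- paths[["T1c"]]
  if (is.null(p_primary) || is.na(p_primary) || !nzchar(p_primary))
    stop("primary channel T1c path is required")
  if (!file.exists(p_primary))
    stop("primary channel file not found: ", p_primary)
  primary <- read_volume(p_primary)
  dims <- dim(primary$voxels)
  spacing <- primary$spacing
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(p_primary))

  check_grid <- function(vol, path) {
    problems <- character(0)
    if (!identical(dim(vol$voxels), dims))
      problems <- c(problems, sprintf(
        "%s: shape %s != %s", path,
        paste(dim(vol$voxels), collapse = "x"),
        paste(dims, collapse = "x")))
    rel <- abs(vol$spacing - spacing) / spacing
    if (any(rel > SPACING_RTOL))
      problems <- c(problems, sprintf(
        "%s: spacing (%s) mm != (%s) mm", path,
        paste(signif(vol$spacing, 6), collapse = ", "),
        paste(signif(spacing, 6), collapse = ", ")))
    problems
  }

  channels <- list()
  available <- logical(0)
  problems <- character(0)
  for (ch in channel_names()) {
    p <- paths[[ch]]
    present <- !is.null(p) && !is.na(p) && nzchar(p)
    if (ch == "T1c") {
      channels[[ch]] <- primary$voxels
      available[[ch]] <- TRUE
    } else if (present) {
      if (!file.exists(p)) stop("channel ", ch, " file not found: ", p)
      vol <- read_volume(p)
      problems <- c(problems, check_grid(vol, p))
      channels[[ch]] <- vol$voxels
      available[[ch]] <- TRUE
    } else {
      channels[[ch]] <- array(0, dim = dims)
      available[[ch]] <- FALSE
    }
  }

  read_mask_file <- function(p) {
    vol <- read_volume(p)
    problems <<- c(problems, check_grid(vol, p))
    m <- vol$voxels
    if (!all(m %in% c(0, 1)))
      stop("mask file is not binary: ", p)
    m
  }
  mask <- NULL
  if (!is.null(paths[["mask"]]) && !is.na(paths[["mask"]]) &&
      nzchar(paths[["mask"]]))
    mask <- read_mask_file(paths[["mask"]])
  brain_mask <- NULL
  if (!is.null(paths[["brain_mask"]]) && !is.na(paths[["brain_mask"]]) &&
      nzchar(paths[["brain_mask"]]))
    brain_mask <- read_mask_file(paths[["brain_mask"]])

  if (length(problems))
    stop("grid mismatch:\n  ", paste(problems, collapse = "\n  "))

  # Without an explicit brain mask, take the support of the primary
  # channel (air is zero in the phantoms and in skull-stripped data).
  if (is.null(brain_mask))
    brain_mask <- array(as.numeric(primary$voxels != 0), dim = dims)
  if (!is.null(mask)) mask <- mask * brain_mask

  mri_subject(subject_id, channels, available, spacing, brain_mask, mask)
}

#' Write a binary mask as NIfTI
#'
#' Masks are stored as unsigned 8-bit with the mask's spacing in the
#' header; a round-trip read returns bit-identical voxels and spacing.
#'
#' @param mask A \code{\link{seg_mask}}.
#' @param path Output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels),
                               dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @param path NIfTI file path.
#' @return A \code{\link{seg_mask}}.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  seg_mask(vol$voxels, vol$spacing)
}

write_scalar_volume <- function(voxels, spacing, path) {
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns \code{subject_id},
#' \code{split} (train/val/test), one path column per channel (empty
#' cell = missing channel), \code{mask}, and optionally
#' \code{brain_mask}.  Relative paths are resolved against the manifest
#' directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with resolved paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("subject_id", "split", channel_names(), "mask")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(man$split %in% c("train", "val", "test")))
    stop("split must be one of train/val/test")
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject_id in manifest")
  root <- dirname(normalizePath(path))
  path_cols <- intersect(c(channel_names(), "mask", "brain_mask"),
                         names(man))
  for (col in path_cols) {
    p <- man[[col]]
    rel <- nzchar(p) & !grepl("^/", p)
    p[rel] <- file.path(root, p[rel])
    man[[col]] <- p
  }
  man
}

#' Read all subjects of one split from a manifest
#'
#' @param manifest Data.frame from \code{\link{read_manifest}}.
#' @param split One of "train", "val", "test", or NULL for all rows.
#' @return List of \code{\link{mri_subject}} objects.
#' @export
read_split <- function(manifest, split = NULL) {
  rows <- if (is.null(split)) manifest else
    manifest[manifest$split == split, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    paths <- as.list(r[intersect(c(channel_names(), "mask", "brain_mask"),
                                 names(r))])
    paths <- lapply(paths, function(p) if (nzchar(p)) p else NA_character_)
    read_subject(paths, subject_id = r$subject_id)
  })
}
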