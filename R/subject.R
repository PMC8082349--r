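#' @keywords internal
#' @useDynLib sparseseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Channel names in their fixed global order
#'
#' The channel order is fixed package-wide as (T1c, T1w, T2w, FLAIR).
#' T1c (post-contrast T1-weighted) is the primary channel: it is required
#' for every subject and is never zeroed by the sparsification layer.
#' The remaining three are the secondary channels, which may be missing.
#'
#' @return Character vector of the four channel names, primary first.
#' @export
channel_names <- function() c("T1c", "T1w", "T2w", "FLAIR")

#' Secondary (possibly missing) channel names
#' @return Character vector of the three secondary channel names.
#' @export
secondary_channels <- function() c("T1w", "T2w", "FLAIR")

#' Construct a subject: a co-registered multi-channel stack
#'
#' A subject bundles the four co-registered channel volumes, per-channel
#' availability flags, the voxel spacing, a brain support mask, and an
#' optional ground-truth tumor-core mask.  Channels flagged unavailable
#' must be identically zero; the primary channel (T1c) must be available.
#'
#' @param subject_id Opaque identifier string.
#' @param channels Named list of 3D numeric arrays, one per channel in
#'   \code{channel_names()} order; all the same dimensions.
#' @param available Named logical vector over the channels.
#' @param spacing Numeric length-3 voxel size in mm.
#' @param brain_mask Binary 3D array (1 = inside head/brain support).
#' @param mask Optional binary 3D array (1 = tumor core), or NULL.
#' @param validate Run invariant checks (default TRUE).
#' @return An object of class \code{mri_subject}.
#' @export
mri_subject <- function(subject_id, channels, available, spacing,
                        brain_mask, mask = NULL, validate = TRUE) {
  obj <- structure(
    list(subject_id = as.character(subject_id),
         channels = channels,
         available = available,
         spacing = as.numeric(spacing),
         brain_mask = brain_mask,
         mask = mask),
    class = "mri_subject")
  if (validate) validate_subject(obj)
  obj
}

#' Validate the subject invariants
#'
#' Checks: fixed channel order, identical grid across all volumes,
#' primary channel available, unavailable channels exactly zero, binary
#' masks, and tumor mask contained in the brain mask.
#'
#' @param subject An \code{mri_subject}.
#' @return The subject, invisibly; stops on violation.
#' @export
validate_subject <- function(subject) {
  ch <- channel_names()
  if (!identical(names(subject$channels), ch))
    stop("channels must be named ", paste(ch, collapse = ", "),
         " in that order")
  if (!identical(sort(names(subject$available)), sort(ch)))
    stop("available flags must cover all four channels")
  dims <- dim(subject$channels[[1]])
  if (length(dims) != 3L) stop("channel volumes must be 3D")
  for (c in ch) {
    if (!identical(dim(subject$channels[[c]]), dims))
      stop("channel ", c, " has mismatched dimensions")
  }
  if (!identical(dim(subject$brain_mask), dims))
    stop("brain_mask dimensions do not match the channels")
  if (length(subject$spacing) != 3L || any(subject$spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm")
  if (!isTRUE(subject$available[["T1c"]]))
    stop("primary channel T1c must be available")
  for (c in ch) {
    if (!subject$available[[c]] && max(abs(subject$channels[[c]])) > 0)
      stop("channel ", c, " flagged unavailable but not identically zero")
  }
  if (!all(subject$brain_mask %in% c(0, 1)))
    stop("brain_mask must be binary")
  if (!is.null(subject$mask)) {
    if (!identical(dim(subject$mask), dims))
      stop("mask dimensions do not match the channels")
    if (!all(subject$mask %in% c(0, 1)))
      stop("mask must be binary")
    if (any(subject$mask > subject$brain_mask))
      stop("tumor mask must be contained in the brain mask")
  }
  invisible(subject)
}

#' @export
print.mri_subject <- function(x, ...) {
  dims <- dim(x$channels[[1]])
  cat("<mri_subject>", x$subject_id, "\n")
  cat("  grid: ", paste(dims, collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  avail <- vapply(channel_names(), function(c) x$available[[c]], logical(1))
  cat("  channels:",
      paste(sprintf("%s%s", channel_names(),
                    ifelse(avail, "", " (missing)")), collapse = ", "),
      "\n")
  if (!is.null(x$mask))
    cat("  tumor core: ", sum(x$mask), " voxels\n", sep = "")
  invisible(x)
}

#' Construct a segmentation mask
#'
#' @param voxels Binary 3D array (values 0/1).
#' @param spacing Numeric length-3 voxel size in mm.
#' @return An object of class \code{seg_mask}.
#' @export
seg_mask <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L) stop("mask must be 3D")
  if (!all(voxels %in% c(0, 1))) stop("mask values must be 0/1")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("<seg_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " foreground\n", sep = "")
  invisible(x)
}

# Deterministic 31-bit seed derivation: keeps every derived seed a valid
# 32-bit R integer and decorrelates streams via distinct salts.
derive_seed <- function(master, salt, i = 0L) {
  m <- 2147483629
  x <- (as.double(master) %% m) * 48271 + as.double(salt) * 9973 +
    as.double(i) * 7919 + 12345
  as.integer(x %% m)
}
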