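# Evaluation measures for (manual, automatic) mask pairs: Dice overlap,
# sensitivity, and the undirected 95th-percentile Hausdorff distance
# between segmentation boundaries in mm.

as_mask_voxels <- function(m) {
  if (inherits(m, "seg_mask")) m$voxels else m
}

check_same_grid <- function(manual, automatic) {
  vm <- as_mask_voxels(manual)
  va <- as_mask_voxels(automatic)
  if (!identical(dim(vm), dim(va)))
    stop("mask grids do not match: ",
         paste(dim(vm), collapse = "x"), " vs ",
         paste(dim(va), collapse = "x"))
  if (inherits(manual, "seg_mask") && inherits(automatic, "seg_mask") &&
      max(abs(manual$spacing - automatic$spacing)) > 1e-8)
    stop("mask spacings do not match")
  list(m = vm, a = va)
}

confusion_counts <- function(manual, automatic) {
  g <- check_same_grid(manual, automatic)
  tp <- sum(g$m == 1 & g$a == 1)
  fp <- sum(g$m == 0 & g$a == 1)
  fn <- sum(g$m == 1 & g$a == 0)
  list(tp = tp, fp = fp, fn = fn)
}

#' Dice overlap between manual and automatic segmentations
#'
#' \code{2 TP / (2 TP + FP + FN)}; symmetric in its arguments.  If both
#' masks are empty the score is 1 by convention (flagged via the
#' \code{both_empty} attribute).
#'
#' @param manual,automatic Binary masks (\code{\link{seg_mask}} or 3D
#'   arrays) on the same grid.
#' @return Dice score in [0, 1].
#' @export
dice_score <- function(manual, automatic) {
  cc <- confusion_counts(manual, automatic)
  den <- 2 * cc$tp + cc$fp + cc$fn
  if (den == 0) return(structure(1, both_empty = TRUE))
  2 * cc$tp / den
}

#' Sensitivity (recall) of the automatic segmentation
#'
#' \code{TP / (TP + FN)}.  Undefined (NA) when the manual mask is empty.
#'
#' @inheritParams dice_score
#' @return Sensitivity in [0, 1], or NA.
#' @export
sensitivity_score <- function(manual, automatic) {
  cc <- confusion_counts(manual, automatic)
  if (cc$tp + cc$fn == 0) return(NA_real_)
  cc$tp / (cc$tp + cc$fn)
}

# Boundary voxels under 6-connectivity: a mask voxel is boundary iff any
# face neighbour is background or lies outside the volume.
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- array(0, d)
      src <- lapply(d, seq_len)
      dst <- src
      n <- d[ax]
      if (dir == 1L) { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
      else { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
      nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
      interior <- interior & (nb == 1)
    }
  }
  mask == 1 & !interior
}

boundary_coords_mm <- function(mask, spacing) {
  idx <- which(boundary_voxels(mask))
  if (!length(idx)) return(matrix(numeric(0), 0, 3))
  sweep(arrayInd(idx, dim(mask)), 2, spacing, "*")
}

# For each row of A (n x 3, mm), the distance to the nearest row of B,
# computed blockwise from the squared-norm expansion so the inner loop
# is a BLAS product.
nearest_distances <- function(A, B, block = 1024L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = block)) {
    e <- min(s + block - 1L, nrow(A))
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), nb2, "+") - 2 * tcrossprod(Ab, B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Undirected 95th-percentile Hausdorff distance (mm)
#'
#' Boundary voxel sets of both masks are extracted (6-connectivity
#' border, voxel centers in mm under the anisotropic spacing); for each
#' direction the 95th percentile (linear interpolation between order
#' statistics) of the nearest-neighbour distances is taken, and the
#' undirected value is the maximum of the two directed percentiles.
#' \code{method = "pooled"} instead takes the percentile of the pooled
#' distance set.  Undefined (NA) when either mask is empty.
#'
#' @inheritParams dice_score
#' @param spacing Per-axis voxel size in mm.
#' @param percentile Percentile in (0, 100]; default 95.
#' @param method "max" (default) or "pooled".
#' @return Distance in mm, or NA if either mask is empty.
#' @export
hd95_undirected <- function(manual, automatic, spacing = c(1, 1, 1),
                            percentile = 95, method = c("max", "pooled")) {
  method <- match.arg(method)
  g <- check_same_grid(manual, automatic)
  if (inherits(manual, "seg_mask")) spacing <- manual$spacing
  if (sum(g$m) == 0 || sum(g$a) == 0) return(NA_real_)
  Pm <- boundary_coords_mm(g$m, spacing)
  Pa <- boundary_coords_mm(g$a, spacing)
  d_am <- nearest_distances(Pa, Pm)   # automatic -> manual
  d_ma <- nearest_distances(Pm, Pa)   # manual -> automatic
  q <- percentile / 100
  if (method == "pooled")
    return(as.numeric(stats::quantile(c(d_am, d_ma), q, type = 7)))
  max(as.numeric(stats::quantile(d_am, q, type = 7)),
      as.numeric(stats::quantile(d_ma, q, type = 7)))
}

#' Evaluate one (manual, automatic) pair on all three measures
#'
#' One consistent set of confusion counts feeds Dice and sensitivity;
#' HD95 is computed on the same grids.  Empty-mask conventions:
#' Dice(empty, empty) = 1, sensitivity undefined for an empty manual
#' mask, HD95 undefined if either mask is empty; sentinels are carried
#' in the \code{flags} field rather than dropped.
#'
#' @inheritParams hd95_undirected
#' @return One-row data.frame with dice, sensitivity, hd95, tp, fp, fn
#'   and flags.
#' @export
evaluate_pair <- function(manual, automatic, spacing = c(1, 1, 1)) {
  cc <- confusion_counts(manual, automatic)
  flags <- character(0)
  den <- 2 * cc$tp + cc$fp + cc$fn
  dice <- if (den == 0) { flags <- c(flags, "both_empty"); 1 }
          else 2 * cc$tp / den
  sens <- if (cc$tp + cc$fn == 0) {
    flags <- c(flags, "manual_empty"); NA_real_
  } else cc$tp / (cc$tp + cc$fn)
  g <- check_same_grid(manual, automatic)
  hd <- if (sum(g$m) == 0 || sum(g$a) == 0) {
    flags <- c(flags, "hd95_undefined"); NA_real_
  } else hd95_undirected(manual, automatic, spacing)
  data.frame(dice = as.numeric(dice), sensitivity = sens, hd95 = hd,
             tp = cc$tp, fp = cc$fp, fn = cc$fn,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
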