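# Grey-level vessel segmentation: parenchyma extraction, inversion so
# air-filled lumina become foreground, and morphological cleanup.
#
# Connectivity convention throughout: foreground 26-connected, background
# 6-connected (the standard dual pair, which avoids topological paradoxes
# and matches the skeletonization stage).

#' Otsu threshold of 8-bit grey values
#'
#' Exhaustive search over the 0..255 histogram for the threshold
#' maximizing between-class variance.
#'
#' @param values integer grey values in 0..255.
#' @return The threshold `t`; foreground is `value > t`.
#' @export
otsu_threshold <- function(values) {
  h <- tabulate(as.integer(values) + 1L, nbins = 256L)
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(h) / n
  m0 <- cumsum(h * lv) / n
  mt <- m0[256]
  between <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  which.max(between) - 1L
}

#' Count connected components of a binary mask
#'
#' @param mask binary [voxel_volume()] or array.
#' @param connectivity 26 (foreground default) or 6.
#' @return Integer component count.
#' @export
count_components <- function(mask, connectivity = 26) {
  m <- as_mask_array(mask)
  max(cpp_label(m, dim(m), as.integer(connectivity)), 0L)
}

# fill interior cavities: background 6-components not touching the border
fill_holes <- function(mask_arr) {
  inv <- array(as.integer(!mask_arr), dim(mask_arr))
  lab <- cpp_label(inv, dim(inv), 6L)
  d <- dim(lab)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border != 0]
  filled <- mask_arr
  filled[lab != 0 & !(lab %in% border)] <- 1L
  array(as.integer(filled), dim(mask_arr))
}

# keep the largest 26-connected component
largest_component <- function(mask_arr) {
  lab <- cpp_label(mask_arr, dim(mask_arr), 26L)
  if (max(lab) == 0L) return(mask_arr)
  sizes <- tabulate(lab[lab > 0])
  array(as.integer(lab == which.max(sizes)), dim(mask_arr))
}

#' Extract the parenchyma hull from a grey volume
#'
#' Grey-level segmentation of the tissue: voxels above the threshold are
#' parenchyma foreground; the largest 26-connected component is kept and
#' its interior cavities are filled, producing the outer hull within which
#' vessel voids are enclosed.  The threshold is chosen by Otsu's method on
#' the grey histogram by default, or fixed for reproducibility.
#'
#' @param grey a [voxel_volume()] with `grey8` payload.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold grey threshold for `method = "fixed"`.
#' @return Object of class `parenchyma_seg`: `hull` (filled hull
#'   [voxel_volume()] mask), `foreground` (thresholded tissue mask) and
#'   `threshold`.
#' @export
segment_parenchyma <- function(grey, method = c("otsu", "fixed"),
                               threshold = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(grey, "voxel_volume"))
  if (grey$payload != "grey8") stop("`grey` must have grey8 payload")
  thr <- switch(method,
                otsu = otsu_threshold(grey$data),
                fixed = {
                  if (is.null(threshold)) stop("`threshold` required")
                  threshold
                })
  fg <- array(as.integer(grey$data > thr), dim(grey$data))
  if (sum(fg) == 0L) stop("empty foreground: nothing above the threshold")
  comp <- largest_component(fg)
  hull <- fill_holes(comp)
  structure(list(
    hull = voxel_volume(hull, grey$voxel_size, "mask"),
    foreground = voxel_volume(fg, grey$voxel_size, "mask"),
    threshold = thr
  ), class = "parenchyma_seg")
}

#' Extract vessel voids from a grey volume
#'
#' Inverts the tissue segmentation inside the sample hull: vessel voxels
#' are the below-threshold voids enclosed by the parenchyma
#' (`NOT foreground AND hull`), which excludes the exterior air by
#' construction.  Raising the parenchyma threshold can only grow the
#' vessel set (anti-monotonicity in the threshold).
#'
#' @param grey a [voxel_volume()] with `grey8` payload.
#' @param hull a [segment_parenchyma()] result, or a hull mask
#'   [voxel_volume()] (then the grey volume is re-thresholded with
#'   `threshold`).
#' @param threshold grey threshold when `hull` is a bare mask.
#' @return Vessel mask [voxel_volume()].
#' @export
extract_vessels <- function(grey, hull, threshold = NULL) {
  stopifnot(inherits(grey, "voxel_volume"))
  if (inherits(hull, "parenchyma_seg")) {
    h <- hull$hull$data
    fg <- hull$foreground$data
  } else {
    h <- as_mask_array(hull)
    if (is.null(threshold))
      stop("`threshold` required when `hull` is a bare mask")
    fg <- array(as.integer(grey$data > threshold), dim(grey$data))
  }
  v <- array(as.integer(h & !fg), dim(h))
  voxel_volume(v, grey$voxel_size, "mask")
}

#' Morphological cleanup of a binary mask
#'
#' 3D opening with a Euclidean ball structuring element of radius
#' `open_radius` voxels (realized exactly through the distance transform:
#' erosion keeps voxels farther than the radius from the background,
#' dilation restores them), followed by removal of 26-connected
#' components smaller than `min_component` voxels.  `open_radius = 0`
#' with `min_component = 1` is the identity; cleaning is idempotent.
#'
#' @param mask binary [voxel_volume()].
#' @param open_radius ball radius in voxels (>= 0).
#' @param min_component minimum component size in voxels.
#' @return Cleaned mask [voxel_volume()].
#' @export
morphological_clean <- function(mask, open_radius = 1, min_component = 27) {
  m <- as_mask_array(mask)
  if (open_radius > 0) {
    er <- array(as.integer(cpp_edt_sq(m, dim(m)) > open_radius^2 + 1e-9),
                dim(m))
    inv <- array(as.integer(!er), dim(er))
    m <- array(as.integer(cpp_edt_sq(inv, dim(inv)) <=
                            open_radius^2 + 1e-9), dim(er))
    # note: EDT of !er measures distance to the eroded set for background
    # voxels; eroded voxels themselves have distance 0 there
  }
  if (min_component > 1) {
    lab <- cpp_label(m, dim(m), 26L)
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_component)
      m <- array(as.integer(lab %in% keep), dim(m))
    }
  }
  voxel_volume(m, vol_voxel_size(mask), "mask")
}
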