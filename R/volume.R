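#' Voxel volume container
#'
#' A 3D scalar grid with a physical voxel size.  The array is ordered
#' `(z, y, x)` with `z` the slice index (slice 0 = dorsal-most when the
#' volume comes out of reconstruction); voxel indices are 0-based and
#' positions refer to voxel centers, so the center of voxel `(i, j, k)`
#' sits at `c(i, j, k) * voxel_size` micrometers.
#'
#' @param data 3D numeric or integer array, dim `(nz, ny, nx)`.
#' @param voxel_size edge length of a voxel in micrometers.
#' @param payload one of `"grey_float"`, `"grey8"`, `"mask"`, `"distance"`.
#'   `grey8` values must lie in `[0, 255]`; `mask` values in `{0, 1}`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size,
                         payload = c("grey_float", "grey8", "mask",
                                     "distance")) {
  payload <- match.arg(payload)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometers)")
  if (payload == "mask") {
    if (!all(data %in% c(0, 1)))
      stop("mask payload must contain only 0 and 1")
    data <- array(as.integer(data), dim(data))
  }
  if (payload == "grey8" && (min(data) < 0 || max(data) > 255))
    stop("grey8 payload must lie in [0, 255]")
  structure(list(data = data, voxel_size = voxel_size, payload = payload),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %s payload, %d x %d x %d (z,y,x), %.4g um/voxel\n",
              x$payload, d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# accept either a voxel_volume or a bare array; returns the array
as_vol_array <- function(x) {
  if (inherits(x, "voxel_volume")) x$data else x
}

vol_voxel_size <- function(x, voxel_size = NULL) {
  if (!is.null(voxel_size)) return(voxel_size)
  if (inherits(x, "voxel_volume")) return(x$voxel_size)
  stop("`voxel_size` must be given when the input is a bare array")
}

as_mask_array <- function(x) {
  a <- as_vol_array(x)
  if (!all(a %in% c(0, 1))) stop("expected a binary mask")
  array(as.integer(a), dim(a))
}

#' Write a volume as a multi-page 8-bit TIFF stack
#'
#' Masks are written as 0/255, grey8 as stored; one page per z-slice.
#' A JSON sidecar (`<path>.json`) records the voxel size and payload so
#' the stack can be read back without guessing.
#'
#' @param vol a [voxel_volume()] with `mask` or `grey8` payload.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  a <- vol$data
  if (vol$payload == "mask") a <- a * 255L
  if (vol$payload %in% c("grey_float", "distance"))
    stop("write_volume_tiff supports mask and grey8 payloads")
  pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(voxel_size_um = vol$voxel_size, payload = vol$payload,
         dim_zyx = dim(a)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack into a voxel volume
#'
#' Accepts stacks written by [write_volume_tiff()] (sidecar JSON honoured)
#' or any grey-scale multi-page TIFF, in which case `voxel_size` and
#' `payload` must be supplied.
#'
#' @param path TIFF file path.
#' @param voxel_size voxel edge in micrometers (overrides sidecar).
#' @param payload payload kind (overrides sidecar).
#' @return A [voxel_volume()].
#' @export
read_volume_tiff <- function(path, voxel_size = NULL, payload = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(voxel_size)) voxel_size <- meta$voxel_size_um
    if (is.null(payload)) payload <- meta$payload
  }
  if (is.null(voxel_size))
    stop("`voxel_size` required (no sidecar JSON found)")
  if (is.null(payload)) payload <- "grey8"
  a <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    a[z, , ] <- pg
  }
  a <- round(a * 255)
  if (payload == "mask") a <- array(as.integer(a > 127), dim(a))
  voxel_volume(a, voxel_size, payload)
}

# run code with a temporarily-seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
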