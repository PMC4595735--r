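#' Photon energy to X-ray wavelength
#'
#' Converts a photon energy in keV to its wavelength using the CODATA
#' value of `h c / e` (1.23984198 keV nm).
#'
#' @param energy_kev photon energy in keV (> 0).
#' @return Wavelength in micrometers.
#' @examples
#' energy_to_wavelength(12.3984198)  # 1e-4 um = 1 Angstrom
#' @export
energy_to_wavelength <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(energy_kev <= 0))
    stop("`energy_kev` must be positive")
  hc_kev_nm <- 1.23984198
  (hc_kev_nm / energy_kev) * 1e-3  # nm -> um
}

#' Physical extent of a pixel row/column
#'
#' @param n_pixels number of pixels (>= 0).
#' @param pixel_size pixel pitch in micrometers (> 0).
#' @return Extent in micrometers, `n_pixels * pixel_size`.
#' @examples
#' field_extent(1933, 5.92)  # 11443.36
#' @export
field_extent <- function(n_pixels, pixel_size) {
  if (any(n_pixels < 0)) stop("`n_pixels` must be non-negative")
  if (any(pixel_size <= 0)) stop("`pixel_size` must be positive")
  n_pixels * pixel_size
}

#' Fresnel number of one detector pixel
#'
#' `pixel_size^2 / (wavelength * distance)`: a per-pixel measure of how
#' close the imaging setup is to the near-field regime assumed by
#' transport-of-intensity phase retrieval.  Values well above 1 mean
#' near-field; a warning is emitted below 0.1.
#'
#' @param pixel_size detector pixel pitch (micrometers, > 0).
#' @param wavelength X-ray wavelength (micrometers, > 0).
#' @param distance_z propagation distance (micrometers, >= 0); `0` returns
#'   `Inf`.
#' @return Dimensionless Fresnel number.
#' @export
fresnel_number <- function(pixel_size, wavelength, distance_z) {
  if (pixel_size <= 0 || wavelength <= 0 || distance_z < 0)
    stop("pixel_size and wavelength must be > 0 and distance_z >= 0")
  if (distance_z == 0) return(Inf)
  nf <- pixel_size^2 / (wavelength * distance_z)
  if (nf < 0.1)
    warning(sprintf(paste0("Fresnel number %.3g < 0.1: far from the ",
                           "near-field regime assumed by TIE retrieval"), nf))
  nf
}

#' Scan geometry record
#'
#' Bundles the acquisition parameters of a parallel-beam propagation-based
#' scan.  The wavelength is always derived from the energy and never stored
#' independently.  Internal length unit is micrometers throughout the
#' package; angles are stated in degrees and converted to radians only
#' inside numerical kernels.
#'
#' The defaults are a 20 keV beam, 5.92 um detector pixels, 50 cm
#' sample-to-detector distance and 720 projections over 180 degrees with a
#' 963 x 1933 pixel frame -- a whole-brain synchrotron vascular-imaging
#' configuration in which one detector height does not cover the sample, so
#' the object is captured as two vertically overlapping half-scans.
#'
#' @param energy_kev photon energy (keV, > 0).
#' @param pixel_size_um detector pixel pitch (micrometers, > 0).
#' @param distance_um sample-to-detector propagation distance
#'   (micrometers, >= 0).
#' @param n_angles number of projections (>= 1).
#' @param angular_range_deg total angular sweep (degrees, in (0, 360]).
#' @param detector_shape frame shape `c(height_px, width_px)`.
#' @return An object of class `scan_geometry` with a derived
#'   `wavelength_um` field.
#' @export
scan_geometry <- function(energy_kev = 20.0, pixel_size_um = 5.92,
                          distance_um = 50e4, n_angles = 720,
                          angular_range_deg = 180,
                          detector_shape = c(963L, 1933L)) {
  if (energy_kev <= 0) stop("`energy_kev` must be positive")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  if (distance_um < 0) stop("`distance_um` must be non-negative")
  if (n_angles < 1) stop("`n_angles` must be at least 1")
  if (angular_range_deg <= 0 || angular_range_deg > 360)
    stop("`angular_range_deg` must lie in (0, 360]")
  if (length(detector_shape) != 2L || any(detector_shape < 1))
    stop("`detector_shape` must be c(height_px, width_px)")
  structure(list(
    energy_kev = energy_kev,
    wavelength_um = energy_to_wavelength(energy_kev),
    pixel_size_um = pixel_size_um,
    distance_um = distance_um,
    n_angles = as.integer(n_angles),
    angular_range_deg = angular_range_deg,
    detector_shape = as.integer(detector_shape)
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(paste0("<scan_geometry> %.4g keV (lambda %.4g um), pixel ",
                     "%.4g um, z %.4g um,\n  %d angles over %g deg, ",
                     "detector %d x %d px\n"),
              x$energy_kev, x$wavelength_um, x$pixel_size_um, x$distance_um,
              x$n_angles, x$angular_range_deg,
              x$detector_shape[1], x$detector_shape[2]))
  invisible(x)
}

#' Scan angles of a geometry
#'
#' Evenly spaced projection angles in degrees over the angular range,
#' starting at 0 and excluding the closing angle (the 180-degree view
#' duplicates the 0-degree view in parallel beam).
#'
#' @param geometry a [scan_geometry()].
#' @return Numeric vector of length `n_angles`.
#' @export
scan_angles <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  seq(0, geometry$angular_range_deg, length.out = geometry$n_angles + 1L)[
    seq_len(geometry$n_angles)]
}

#' Read a scan geometry from a YAML config
#'
#' Expects a top-level `geometry:` block with keys `energy_kev`,
#' `pixel_size_um`, `distance_cm`, `n_angles`, `angular_range_deg` and
#' `detector_shape`.  Distances are given in cm in configs (the usual
#' beamline bookkeeping unit) and converted to micrometers on read; all
#' internal arithmetic is in micrometers.
#'
#' @param path YAML file; the default is the configuration shipped with the
#'   package (20 keV, 5.92 um, 50 cm, 720 angles / 180 deg, 963 x 1933).
#' @return A [scan_geometry()].
#' @export
read_geometry_config <- function(path = system.file("extdata",
                                                    "default_geometry.yaml",
                                                    package = "angiotomo")) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  if (is.null(g)) stop("config has no `geometry:` block")
  scan_geometry(
    energy_kev = g$energy_kev,
    pixel_size_um = g$pixel_size_um,
    distance_um = g$distance_cm * 1e4,
    n_angles = g$n_angles,
    angular_range_deg = g$angular_range_deg,
    detector_shape = unlist(g$detector_shape)
  )
}
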