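# Acquisition simulator: Radon line integrals of the delta/beta grids,
# Fresnel free-space propagation to the detector, flat/dark fields,
# Poisson counting noise, and the two-half-scan capture mode.

# mirror (symmetric) index map for reflective padding: 0-based out indices
reflect_index <- function(n_out, n) {
  j <- (0:(n_out - 1)) %% (2 * n)
  ifelse(j < n, j, 2 * n - 1 - j) + 1L
}

pad_reflect <- function(img, nr, nc) {
  img[reflect_index(nr, nrow(img)), reflect_index(nc, ncol(img))]
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# FFT sample frequencies in cycles per unit, numpy-fftfreq layout
fft_freq <- function(n, d) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * d)
}

#' Parallel-beam projections of a material volume
#'
#' Line integrals of the `delta` and `beta` grids: for each angle the
#' volume is rotated about the vertical (z) axis and summed along the beam
#' with bilinear in-plane interpolation at unit-voxel steps, scaled by the
#' voxel size so the output is in micrometer-weighted index units.  The
#' operator is linear in the input.
#'
#' @param material a [to_material_volume()] result, or a plain 3D array
#'   (then `voxel_size` is required and a single stack is returned).
#' @param angles_deg projection angles in degrees, within `[0, 360)`.
#' @param voxel_size voxel edge (micrometers), for bare-array input.
#' @return For a material volume, `list(delta = , beta = )` of arrays with
#'   dim `(n_angles, nz, n_detector)`; for a bare array, one such array.
#' @export
project_volume <- function(material, angles_deg, voxel_size = NULL) {
  if (any(angles_deg < 0 | angles_deg >= 360))
    stop("angles must lie in [0, 360)")
  ang <- angles_deg * pi / 180
  if (inherits(material, "material_volume")) {
    list(
      delta = cpp_project(material$delta, dim(material$delta), ang) *
        material$voxel_size,
      beta = cpp_project(material$beta, dim(material$beta), ang) *
        material$voxel_size
    )
  } else {
    a <- as_vol_array(material)
    vs <- vol_voxel_size(material, voxel_size)
    cpp_project(a, dim(a), ang) * vs
  }
}

#' Fresnel free-space propagation of one projection
#'
#' Forms the exit wave behind the object -- phase
#' `phi = -(2 pi / lambda) * projected_delta` and amplitude attenuation
#' `exp(-(2 pi / lambda) * projected_beta)` -- and propagates it to the
#' detector with the Fresnel transfer function
#' `H(u, v) = exp(-i pi lambda z (u^2 + v^2))` applied in Fourier space
#' (`u`, `v` in cycles per micrometer, sampled from the pixel size).
#' Frames are reflect-padded to at least twice the next power of two to
#' suppress wrap-around fringes.  Returns the intensity `|wave|^2`; unit
#' incident intensity gives 1 in empty regions.  At `z = 0` this reduces
#' exactly to Beer-Lambert absorption.
#'
#' @param projected_delta,projected_beta matrices (detector rows x
#'   columns) of projected delta/beta in micrometer units.
#' @param geometry a [scan_geometry()] (uses `wavelength_um`,
#'   `pixel_size_um`, `distance_um`).
#' @return Intensity matrix of the same shape.
#' @export
fresnel_propagate <- function(projected_delta, projected_beta, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  lam <- geometry$wavelength_um
  z <- geometry$distance_um
  px <- geometry$pixel_size_um
  k <- 2 * pi / lam
  wave <- exp(-k * (projected_beta + 1i * projected_delta))
  if (z == 0) return(Mod(wave)^2)
  nr <- nrow(wave); nc <- ncol(wave)
  nrp <- next_pow2(2 * nr); ncp <- next_pow2(2 * nc)
  wp <- pad_reflect(wave, nrp, ncp)
  fu <- fft_freq(nrp, px)  # rows
  fv <- fft_freq(ncp, px)  # cols
  h <- exp(-1i * pi * lam * z *
             (matrix(fu^2, nrp, ncp) + matrix(fv^2, nrp, ncp, byrow = TRUE)))
  out <- fft(fft(wp) * h, inverse = TRUE) / (nrp * ncp)
  Mod(out[seq_len(nr), seq_len(nc)])^2
}

#' Projection set container
#'
#' A stack of detector frames with its angle list, flat/dark calibration
#' frames and geometry.  Frames are photon-count scale intensities with
#' dim `(n_angles, rows, cols)`.
#'
#' @param frames intensity stack, dim `(n_angles, rows, cols)`, all >= 0.
#' @param angles_deg projection angles (degrees), one per frame.
#' @param flat,dark calibration frames (`flat > dark` elementwise).
#' @param geometry a [scan_geometry()].
#' @param half_id `"full"`, `"upper"` or `"lower"`.
#' @return Object of class `projection_set`.
#' @export
projection_set <- function(frames, angles_deg, flat, dark, geometry,
                           half_id = c("full", "upper", "lower")) {
  half_id <- match.arg(half_id)
  if (dim(frames)[1] != length(angles_deg))
    stop("frame count must equal angle count")
  if (min(frames) < 0) stop("intensities must be non-negative")
  if (!all(flat > dark)) stop("flat must exceed dark elementwise")
  structure(list(frames = frames, angles_deg = angles_deg, flat = flat,
                 dark = dark, geometry = geometry, half_id = half_id),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<projection_set> %s: %d frames of %d x %d px\n",
              x$half_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate an acquisition
#'
#' Projects the phantom at the geometry's angles, Fresnel-propagates each
#' projection, and turns intensities into detector counts:
#' `raw = dark + flat * I` with Poisson noise on the detected counts and
#' Gaussian read noise folded into the dark frames.  The flat field
#' carries a smooth deterministic vignetting profile so flat/dark
#' correction is exercised for real.  When `split = TRUE` the capture
#' emulates a sample taller than the detector: two half-scans whose
#' detector rows overlap by `overlap_px` (default 200 px, the standard
#' hemi-scan overlap) are returned.
#'
#' @param material a [to_material_volume()] result.
#' @param geometry a [scan_geometry()]; its detector shape is ignored in
#'   favour of the phantom's own frame size.
#' @param seed integer seed for all noise draws; identical seeds give
#'   identical frames.
#' @param photons_per_pixel incident photons per detector pixel (> 0).
#' @param noise logical; `FALSE` disables all noise, making
#'   `raw = dark + flat * I` exact.
#' @param split logical; emit two vertically overlapping half-scans.
#' @param overlap_px detector-row overlap of the two halves (< frame
#'   height).
#' @param read_noise_sd Gaussian read noise, counts RMS.
#' @param n_flat flat-field frames averaged into the stored flat.
#' @return A `projection_set`, or `list(upper = , lower = )` of them when
#'   `split = TRUE`.
#' @export
acquire <- function(material, geometry, seed = 1,
                    photons_per_pixel = 1e4, noise = TRUE, split = FALSE,
                    overlap_px = 200, read_noise_sd = 0.5, n_flat = 10) {
  stopifnot(inherits(material, "material_volume"))
  if (photons_per_pixel <= 0) stop("`photons_per_pixel` must be positive")
  proj <- project_volume(material, scan_angles(geometry))
  na <- dim(proj$delta)[1]; nz <- dim(proj$delta)[2]; nu <- dim(proj$delta)[3]
  intens <- array(0, c(na, nz, nu))
  for (a in seq_len(na))
    intens[a, , ] <- fresnel_propagate(proj$delta[a, , ], proj$beta[a, , ],
                                       geometry)

  # smooth deterministic vignetting of the beam profile
  rr <- sqrt(outer(((seq_len(nz) - 1) / max(nz - 1, 1) - 0.5)^2,
                   ((seq_len(nu) - 1) / max(nu - 1, 1) - 0.5)^2, "+"))
  flat_true <- photons_per_pixel * (1 - 0.08 * rr / max(rr))
  dark_true <- matrix(0.002 * photons_per_pixel, nz, nu)

  make_set <- function(rows, half_id, geom) {
    ft <- flat_true[rows, , drop = FALSE]
    dt <- dark_true[rows, , drop = FALSE]
    nr <- length(rows)
    if (noise) {
      raw <- array(0, c(na, nr, nu))
      for (a in seq_len(na))
        raw[a, , ] <- dt +
          matrix(rpois(nr * nu, ft * intens[a, rows, ]), nr, nu) +
          matrix(rnorm(nr * nu, 0, read_noise_sd), nr, nu)
      flat_rec <- dt +
        matrix(rowMeans(matrix(rpois(nr * nu * n_flat, rep(ft, n_flat)),
                               nr * nu, n_flat)), nr, nu) +
        matrix(rnorm(nr * nu, 0, read_noise_sd / sqrt(n_flat)), nr, nu)
      dark_rec <- dt + matrix(rnorm(nr * nu, 0, read_noise_sd / sqrt(n_flat)),
                              nr, nu)
      raw[raw < 0] <- 0
    } else {
      raw <- array(0, c(na, nr, nu))
      for (a in seq_len(na)) raw[a, , ] <- dt + ft * intens[a, rows, ]
      flat_rec <- dt + ft
      dark_rec <- dt
    }
    projection_set(raw, scan_angles(geometry), flat_rec, dark_rec, geom,
                   half_id)
  }

  with_seed(seed, {
    if (!split) {
      make_set(seq_len(nz), "full", geometry)
    } else {
      if (overlap_px >= nz)
        stop("`overlap_px` must be smaller than the frame height")
      h <- ceiling((nz + overlap_px) / 2)
      g2 <- geometry
      g2$detector_shape <- c(h, nu)
      list(upper = make_set(seq_len(h), "upper", g2),
           lower = make_set((nz - h + 1):nz, "lower", g2))
    }
  })
}

#' Flat/dark-field correction
#'
#' Normalizes raw counts to incident intensity:
#' `I = (raw - dark) / (flat - dark)`, clipped below at a small positive
#' floor so downstream logarithms stay finite.  The correction is exactly
#' invariant to rescaling flat and dark by a common gain.
#'
#' @param ps a [projection_set()].
#' @param floor_frac positive floor, as a fraction of the mean corrected
#'   intensity.
#' @return Normalized intensity stack, dim `(n_angles, rows, cols)`.
#' @export
flat_dark_correct <- function(ps, floor_frac = 1e-6) {
  stopifnot(inherits(ps, "projection_set"))
  denom <- ps$flat - ps$dark
  if (any(denom <= 0)) stop("flat must exceed dark everywhere")
  na <- dim(ps$frames)[1]
  out <- ps$frames
  for (a in seq_len(na))
    out[a, , ] <- (ps$frames[a, , ] - ps$dark) / denom
  fl <- floor_frac * max(mean(out), .Machine$double.eps)
  out[out < fl] <- fl
  out
}
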