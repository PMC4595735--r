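#' Phase-retrieval parameter record
#'
#' Parameters of single-distance TIE-HOM retrieval (the homogeneous-object
#' transport-of-intensity closed form): the material's delta-over-beta
#' ratio, beam wavelength, propagation distance and detector pixel size.
#' `beta` is optional and only needed to convert the filtered intensity
#' into an absolute projected thickness.
#'
#' The default `delta_beta = 400` is the single-material ratio the
#' pipeline assumes throughout (it is deliberately an empirical knob:
#' in practice it is tuned against a preliminary scan).
#'
#' @param delta_beta delta/beta ratio (> 0).
#' @param wavelength_um beam wavelength (micrometers, > 0).
#' @param distance_um propagation distance (micrometers, >= 0).
#' @param pixel_size_um detector pixel pitch (micrometers, > 0).
#' @param beta absorption index of the material (optional).
#' @param geometry optionally, a [scan_geometry()] from which wavelength,
#'   distance and pixel size are taken.
#' @return Object of class `retrieval_params`.
#' @export
retrieval_params <- function(delta_beta = 400, wavelength_um = NULL,
                             distance_um = NULL, pixel_size_um = NULL,
                             beta = NULL, geometry = NULL) {
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "scan_geometry"))
    wavelength_um <- geometry$wavelength_um
    distance_um <- geometry$distance_um
    pixel_size_um <- geometry$pixel_size_um
  }
  if (delta_beta <= 0) stop("`delta_beta` must be positive")
  if (is.null(wavelength_um) || wavelength_um <= 0)
    stop("`wavelength_um` must be positive")
  if (is.null(distance_um) || distance_um < 0)
    stop("`distance_um` must be non-negative")
  if (is.null(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be positive")
  if (!is.null(beta) && beta <= 0) stop("`beta` must be positive when given")
  structure(list(delta_beta = delta_beta, wavelength_um = wavelength_um,
                 distance_um = distance_um, pixel_size_um = pixel_size_um,
                 beta = beta),
            class = "retrieval_params")
}

#' TIE-HOM low-pass filter of a normalized intensity image
#'
#' The single-distance homogeneous-object filter
#' `F = IFFT[ FFT(I) / (1 + pi lambda z (delta/beta) (u^2 + v^2)) ]`
#' with `(u, v)` in cycles per micrometer.  Padding is reflective and
#' identical to the forward propagator, so forward-then-retrieve
#' round-trip tests isolate algorithmic error.  The zero-frequency gain is
#' 1 (a constant image passes through unchanged) and at `z = 0` the filter
#' is the identity.  The output is floored at a small positive fraction of
#' its mean so it can be logarithmed.
#'
#' @param i_norm normalized intensity image (matrix) or stack
#'   `(n, rows, cols)`.
#' @param params a [retrieval_params()].
#' @param floor_frac positive floor as a fraction of the mean output.
#' @return Filtered image/stack, same shape as the input.
#' @export
tie_hom_filter <- function(i_norm, params, floor_frac = 1e-6) {
  stopifnot(inherits(params, "retrieval_params"))
  if (length(dim(i_norm)) == 3L) {
    out <- i_norm
    for (a in seq_len(dim(i_norm)[1]))
      out[a, , ] <- tie_hom_filter(i_norm[a, , ], params, floor_frac)
    return(out)
  }
  lam <- params$wavelength_um
  z <- params$distance_um
  px <- params$pixel_size_um
  if (z == 0) return(i_norm)
  nr <- nrow(i_norm); nc <- ncol(i_norm)
  nrp <- next_pow2(2 * nr); ncp <- next_pow2(2 * nc)
  ip <- pad_reflect(i_norm, nrp, ncp)
  fu <- fft_freq(nrp, px)
  fv <- fft_freq(ncp, px)
  den <- 1 + pi * lam * z * params$delta_beta *
    (matrix(fu^2, nrp, ncp) + matrix(fv^2, nrp, ncp, byrow = TRUE))
  out <- Re(fft(fft(ip) / den, inverse = TRUE)) / (nrp * ncp)
  out <- out[seq_len(nr), seq_len(nc)]
  fl <- floor_frac * max(mean(out), .Machine$double.eps)
  out[out < fl] <- fl
  out
}

#' Projected thickness by TIE-HOM retrieval
#'
#' Applies [tie_hom_filter()] and inverts Beer-Lambert absorption:
#' `t = -ln(F) / mu` with `mu = 4 pi beta / lambda` the linear absorption
#' coefficient of the (assumed homogeneous) material.  At `z = 0` this is
#' the plain absorption inversion.
#'
#' @param i_norm normalized intensity image (matrix) or stack.
#' @param params a [retrieval_params()] whose `beta` is set.
#' @return Projected thickness map(s) in micrometers.
#' @export
retrieve_thickness <- function(i_norm, params) {
  stopifnot(inherits(params, "retrieval_params"))
  if (is.null(params$beta))
    stop(paste0("`params$beta` is required for absolute thickness; use ",
                "tie_hom_filter() for relative maps"))
  mu <- 4 * pi * params$beta / params$wavelength_um
  f <- tie_hom_filter(i_norm, params)
  -log(f) / mu
}
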