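# Filtered back-projection, 8-bit grey rescale, and FFT phase-correlation
# stitching of the two half-scans.

# frequency response of the band-limited ramp filter (Kak-Slaney discrete
# kernel), optionally apodized; length np, detector sampling delta
ramp_response <- function(np, delta, filter_name = c("ramlak",
                                                     "shepp-logan")) {
  filter_name <- match.arg(filter_name)
  h <- numeric(np)
  idx <- c(0:(np / 2), -(np / 2 - 1):-1)
  h[1] <- 1 / (4 * delta^2)
  odd <- which(idx %% 2 != 0)
  h[odd] <- -1 / (pi * idx[odd] * delta)^2
  resp <- Re(fft(h))
  if (filter_name == "shepp-logan") {
    f <- fft_freq(np, delta)
    fn <- 1 / (2 * delta)
    s <- ifelse(f == 0, 1, sin(pi * f / (2 * fn)) / (pi * f / (2 * fn)))
    resp <- resp * abs(s)
  }
  resp
}

# ramp-filter every row of a sinogram (n_angles x n_u)
filter_sinogram <- function(sino, delta, filter_name = "ramlak") {
  nu <- ncol(sino)
  np <- next_pow2(2 * nu)
  resp <- ramp_response(np, delta, filter_name)
  out <- sino
  for (a in seq_len(nrow(sino))) {
    p <- c(sino[a, ], numeric(np - nu))
    q <- Re(fft(fft(p) * resp, inverse = TRUE)) / np * delta
    out[a, ] <- q[seq_len(nu)]
  }
  out
}

#' Filtered back-projection reconstruction
#'
#' Reconstructs a stack of slices from retrieved projections by
#' parallel-beam filtered back-projection: each detector row is ramp
#' filtered (Ram-Lak by default, Shepp-Logan apodization available) and
#' back-projected with linear interpolation onto a square slice grid of
#' side equal to the detector width.  Angles must be uniformly spaced over
#' about 180 degrees (non-uniform sets are rejected; resampling is out of
#' scope).  Output voxel size equals the detector pixel size, and the
#' operator is linear in the sinogram.
#'
#' A sinogram in micrometer-weighted line-integral units of a quantity `f`
#' reconstructs `f` itself (e.g. projected-thickness input yields the
#' tissue indicator function).
#'
#' @param sinogram_stack array `(n_angles, nz, n_u)` -- one sinogram row
#'   per slice -- or a single `(n_angles, n_u)` matrix.
#' @param angles_deg projection angles (degrees), uniformly spaced.
#' @param pixel_size_um detector pixel pitch (micrometers).
#' @param filter_name `"ramlak"` or `"shepp-logan"`.
#' @return A [voxel_volume()] with `grey_float` payload, dim
#'   `(nz, n_u, n_u)`.
#' @export
fbp_reconstruct <- function(sinogram_stack, angles_deg, pixel_size_um,
                            filter_name = c("ramlak", "shepp-logan")) {
  filter_name <- match.arg(filter_name)
  if (length(dim(sinogram_stack)) == 2L)
    sinogram_stack <- array(sinogram_stack,
                            c(nrow(sinogram_stack), 1,
                              ncol(sinogram_stack)))
  d <- dim(sinogram_stack)
  na <- d[1]; nz <- d[2]; nu <- d[3]
  if (length(angles_deg) != na)
    stop("angle count must match the sinogram")
  if (na > 1) {
    steps <- diff(angles_deg)
    if (max(abs(steps - steps[1])) > 1e-9 * max(abs(steps)))
      stop("angles must be uniformly spaced")
    span <- angles_deg[na] - angles_deg[1] + steps[1]
    if (abs(span - 180) > 15)
      warning(sprintf("angular span %.1f deg is far from 180", span))
  }
  filt <- sinogram_stack
  for (z in seq_len(nz))
    filt[, z, ] <- filter_sinogram(sinogram_stack[, z, , drop = TRUE],
                                   pixel_size_um, filter_name)
  rec <- cpp_backproject_stack(filt, dim(filt), angles_deg * pi / 180) *
    (pi / na)
  voxel_volume(rec, pixel_size_um, "grey_float")
}

#' Re-project a reconstructed volume (consistency check)
#'
#' Radon-projects a reconstructed volume at the given angles in the same
#' discretization as [fbp_reconstruct()], for reconstruction-consistency
#' tests.
#'
#' @param vol a [voxel_volume()].
#' @param angles_deg projection angles (degrees).
#' @return Array `(n_angles, nz, n_u)` in micrometer-weighted units.
#' @export
reproject <- function(vol, angles_deg) {
  a <- as_vol_array(vol)
  cpp_project(a, dim(a), angles_deg * pi / 180) * vol_voxel_size(vol)
}

#' Rescale a float volume to 8-bit grey
#'
#' Truncates the intensity scale at the given percentiles and maps it
#' affinely to 0..255 (round half up): values at or below the low
#' percentile go to 0, at or above the high percentile to 255.  The
#' mapping parameters are attached as the `rescale` attribute (and
#' reported by volume writers) so the transform is invertible up to
#' truncation.  A constant volume degenerates to all zeros with a warning.
#'
#' @param vol [voxel_volume()] with `grey_float` payload (or bare array
#'   plus `voxel_size`).
#' @param low_pct,high_pct truncation percentiles,
#'   `0 <= low_pct < high_pct <= 100`.
#' @param voxel_size for bare-array input.
#' @return A [voxel_volume()] with `grey8` payload and a `rescale`
#'   attribute `c(low = , high = )` in input units.
#' @export
rescale_grey8 <- function(vol, low_pct = 0.1, high_pct = 99.9,
                          voxel_size = NULL) {
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stop("need 0 <= low_pct < high_pct <= 100")
  a <- as_vol_array(vol)
  vs <- vol_voxel_size(vol, voxel_size)
  qs <- quantile(a, c(low_pct, high_pct) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    warning("degenerate intensity range; output is all zeros")
    out <- voxel_volume(array(0L, dim(a)), vs, "grey8")
    attr(out, "rescale") <- c(low = qs[1], high = qs[2])
    return(out)
  }
  g <- (a - qs[1]) / (qs[2] - qs[1]) * 255
  g <- floor(pmin(pmax(g, 0), 255) + 0.5)
  g[g > 255] <- 255
  out <- voxel_volume(array(as.integer(g), dim(a)), vs, "grey8")
  attr(out, "rescale") <- c(low = qs[1], high = qs[2])
  out
}

#' Translation between two volumes by FFT phase correlation
#'
#' Computes the argmax of the inverse FFT of the normalized cross-power
#' spectrum (phase correlation) between two equally-shaped stacks, giving
#' the integer translation `shift` (z, y, x) such that
#' `stack_b(p) = stack_a(p + shift)` -- `stack_b` reads `stack_a` at an
#' offset of `+shift`, so for two half-scans
#' `find_shift_fft(upper, lower)$shift[1]` is the merged-frame slice index
#' at which the lower half starts.  Stacks of
#' different slice counts are zero-padded to a common shape.  The score is
#' the correlation peak in `[0, 1]`; degenerate (near-constant) inputs
#' yield a low score and are flagged unreliable.
#'
#' @param stack_a,stack_b 3D arrays or [voxel_volume()]s with identical
#'   in-plane shape.
#' @param min_score reliability threshold on the peak score.
#' @return `list(shift = integer z/y/x vector, score = , reliable = )`.
#' @export
find_shift_fft <- function(stack_a, stack_b, min_score = 0.05) {
  a <- as_vol_array(stack_a)
  b <- as_vol_array(stack_b)
  if (!all(dim(a)[2:3] == dim(b)[2:3]))
    stop("stacks must share in-plane shape")
  # zero-pad the slice axis to the joint height: stitching shifts exceed
  # half the stack height, which would alias under circular correlation
  nz <- dim(a)[1] + dim(b)[1]
  pad_z <- function(x, nz) {
    out <- array(0, c(nz, dim(x)[2], dim(x)[3]))
    out[seq_len(dim(x)[1]), , ] <- x - mean(x)
    out
  }
  a <- pad_z(a, nz); b <- pad_z(b, nz)
  fa <- fft(a); fb <- fft(b)
  cp <- fa * Conj(fb)
  m <- Mod(cp)
  eps <- 1e-12 * max(m, .Machine$double.eps)
  r <- Re(fft(cp / (m + eps), inverse = TRUE)) / length(cp)
  peak <- which.max(r)
  idx <- arrayInd(peak, dim(r)) - 1L
  d <- dim(r)
  shift <- as.integer(ifelse(idx > d / 2, idx - d, idx))
  score <- max(min(r[peak], 1), 0)
  reliable <- score >= min_score
  if (!reliable)
    warning(sprintf("phase correlation peak %.3g below %.3g: unreliable",
                    score, min_score))
  list(shift = shift, score = score, reliable = reliable)
}

#' Merge two vertically overlapping half-scan volumes
#'
#' Stitches the `upper` stack (slices 0..n_upper-1) and the `lower` stack,
#' whose first slice sits at slice index `shift[1]` of the merged frame
#' (as returned by [find_shift_fft()] between upper and lower).  The
#' overlapped slices are contributed once -- the lower stack's copies are
#' dropped, optionally cross-faded linearly over the seam -- and the
#' lower stack is rolled in-plane by the y/x components of the shift.
#' Output slice count is `n_upper + n_lower - overlap`.  A negative
#' computed overlap (a gap between the halves) is an error reporting the
#' gap size.
#'
#' @param upper,lower 3D arrays or [voxel_volume()]s.
#' @param shift integer z/y/x shift of `lower` relative to `upper`.
#' @param cross_fade logical; blend linearly across the overlap instead of
#'   cutting at the seam.
#' @param voxel_size for bare-array input.
#' @return A [voxel_volume()] of the merged stack.
#' @export
merge_halves <- function(upper, lower, shift, cross_fade = FALSE,
                         voxel_size = NULL) {
  up <- as_vol_array(upper)
  lo <- as_vol_array(lower)
  vs <- vol_voxel_size(upper, voxel_size)
  if (!all(dim(up)[2:3] == dim(lo)[2:3]))
    stop("halves must share in-plane shape")
  nzu <- dim(up)[1]; nzl <- dim(lo)[1]
  sz <- as.integer(shift[1])
  overlap <- nzu - sz
  if (overlap < 0)
    stop(sprintf("gap of %d slices between the halves", -overlap))
  if (overlap > min(nzu, nzl)) stop("overlap exceeds a half's slice count")
  roll <- function(m, s) {
    # circular in-plane roll by (dy, dx)
    if (all(s == 0)) return(m)
    ny <- nrow(m); nx <- ncol(m)
    m[((seq_len(ny) - 1 - s[1]) %% ny) + 1,
      ((seq_len(nx) - 1 - s[2]) %% nx) + 1]
  }
  nz_out <- nzu + nzl - overlap
  out <- array(0, c(nz_out, dim(up)[2], dim(up)[3]))
  out[seq_len(nzu), , ] <- up
  for (z in seq_len(nzl)) {
    zo <- sz + z
    sl <- roll(lo[z, , ], shift[2:3])
    if (zo > nzu) {
      out[zo, , ] <- sl
    } else if (cross_fade && overlap > 0) {
      w <- (z - 1) / overlap
      out[zo, , ] <- (1 - w) * out[zo, , ] + w * sl
    }  # else: keep the upper half's copy
  }
  voxel_volume(out, vs, if (inherits(upper, "voxel_volume"))
    upper$payload else "grey_float")
}
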