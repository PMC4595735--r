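# End-to-end convenience wrappers: phantom -> acquisition -> retrieval ->
# reconstruction -> segmentation -> network morphometry.

#' Desk-scale scan geometry
#'
#' The acquisition geometry scaled down to a `n`-pixel detector for
#' simulation studies: same beam energy (20 keV), pixel size (5.92 um)
#' and propagation distance (50 cm) as the full-size default, with
#' `n_angles` projections over 180 degrees (180 by default -- a stated
#' scaled-down mode of the full 720-projection scan that keeps test
#' runtimes in minutes; the full mode remains available through
#' [scan_geometry()]).
#'
#' @param n detector width/height in pixels.
#' @param n_angles projections over 180 degrees.
#' @return A [scan_geometry()].
#' @export
desk_geometry <- function(n = 128, n_angles = 180) {
  scan_geometry(energy_kev = 20.0, pixel_size_um = 5.92,
                distance_um = 50e4, n_angles = n_angles,
                angular_range_deg = 180, detector_shape = c(n, n))
}

#' Simulate and reconstruct one phantom scan
#'
#' Runs the whole chain on a seeded vascular phantom: acquisition
#' (Fresnel propagation, flat/dark, Poisson noise), flat/dark correction,
#' per-projection TIE-HOM retrieval (delta/beta = 400), filtered
#' back-projection, and 8-bit grey rescale.
#'
#' @param seed integer seed for the phantom and the noise.
#' @param shape volume shape `c(nz, ny, nx)` (in-plane square).
#' @param n_angles projections over 180 degrees.
#' @param photons_per_pixel incident photons per pixel.
#' @param noise logical; disable for noiseless studies.
#' @param phantom optionally a pre-built [vascular_phantom()] result.
#' @param ... passed to [vascular_phantom()].
#' @return list with the phantom (`tree`, `vessel_mask`,
#'   `parenchyma_mask`, `truth`), `geometry`, `grey` (grey8
#'   [voxel_volume()]) and `recon` (float volume).
#' @export
simulate_scan <- function(seed, shape = c(128, 128, 128), n_angles = 180,
                          photons_per_pixel = 1e4, noise = TRUE,
                          phantom = NULL, ...) {
  if (is.null(phantom)) phantom <- vascular_phantom(seed, shape = shape, ...)
  geom <- desk_geometry(n = shape[3], n_angles = n_angles)
  ps <- acquire(phantom$material, geom, seed = seed,
                photons_per_pixel = photons_per_pixel, noise = noise)
  i_norm <- flat_dark_correct(ps)
  rp <- retrieval_params(delta_beta = 400, geometry = geom, beta = 1)
  thick <- tie_hom_filter(i_norm, rp)
  # reconstruct the absorption-index line integrals: -log keeps the
  # vessel voids dark after reconstruction
  sino <- -log(thick)
  rec <- fbp_reconstruct(sino, ps$angles_deg, geom$pixel_size_um)
  grey <- rescale_grey8(rec)
  c(phantom, list(geometry = geom, recon = rec, grey = grey))
}

#' Segment and quantify a reconstructed phantom scan
#'
#' Vessel segmentation (Otsu by default), morphological cleanup,
#' skeletonization, graph construction and global morphometry, plus the
#' ground-truth recovery report when the phantom truth is available.
#'
#' @param scan a [simulate_scan()] result (or any list with `grey` and
#'   optionally `tree`, `vessel_mask`, `parenchyma_mask`).
#' @param open_radius,min_component see [morphological_clean()].
#' @return list with `vessel_mask` (recovered), `graph`, `metrics`,
#'   `dice` (against ground truth, if available) and `recovery`
#'   (diameter/length report, if available).
#' @export
analyze_scan <- function(scan, open_radius = 1, min_component = 27) {
  seg <- segment_parenchyma(scan$grey, method = "otsu")
  vm <- extract_vessels(scan$grey, seg)
  vm <- morphological_clean(vm, open_radius = open_radius,
                            min_component = min_component)
  sk <- skeletonize(vm)
  dm <- distance_map(vm)
  g <- build_graph(sk, dm)
  sample_mask <- if (!is.null(scan$parenchyma_mask))
    scan$parenchyma_mask else seg$hull
  met <- compute_metrics(g, vm, sample_mask)
  out <- list(vessel_mask = vm, skeleton = sk, distance = dm, graph = g,
              metrics = met, segmentation = seg)
  if (!is.null(scan$vessel_mask)) {
    a <- scan$vessel_mask$data; b <- vm$data
    out$dice <- 2 * sum(a & b) / max(sum(a) + sum(b), 1)
  }
  if (!is.null(scan$tree))
    out$recovery <- diameter_recovery_report(g, scan$tree)
  out
}
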