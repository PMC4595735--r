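# small homogeneous test material: a centred slab of tissue
slab_material <- function(n = 32, t_vox = 10, beta = 1e-9, vsz = 5.92) {
  d <- array(0, c(n, n, n))
  lo <- n / 2 - t_vox / 2 + 1
  hi <- n / 2 + t_vox / 2
  d[, , lo:hi] <- 1
  structure(list(delta = 400 * beta * d, beta = beta * d,
                 voxel_size = vsz), class = "material_volume")
}

test_that("projection is linear and zero on empty volumes", {
  vsz <- 5.92
  z <- structure(list(delta = array(0, c(8, 16, 16)),
                      beta = array(0, c(8, 16, 16)), voxel_size = vsz),
                 class = "material_volume")
  pz <- project_volume(z, c(0, 30, 91))
  expect_equal(max(abs(pz$delta)), 0)
  expect_equal(max(abs(pz$beta)), 0)

  set.seed(1)
  a <- array(runif(8 * 16 * 16), c(8, 16, 16))
  b <- array(runif(8 * 16 * 16), c(8, 16, 16))
  ang <- c(10, 77)
  pa <- project_volume(a, ang, voxel_size = vsz)
  pb <- project_volume(b, ang, voxel_size = vsz)
  pab <- project_volume(2 * a + 3 * b, ang, voxel_size = vsz)
  expect_equal(pab, 2 * pa + 3 * pb, tolerance = 1e-12)
})

test_that("slab projection at 0 degrees is the line integral of a constant", {
  mat <- slab_material(n = 32, t_vox = 10)
  p <- project_volume(mat, 0)
  # beam along x at 0 degrees: every ray through the slab sees t = 10 vox
  mid <- p$beta[1, 16, 16]
  expect_equal(mid, 1e-9 * 10 * 5.92, tolerance = 1e-9)
  expect_equal(p$delta[1, 16, 16], 400 * mid, tolerance = 1e-6)
})

test_that("projection at theta+180 mirrors the projection at theta", {
  set.seed(2)
  a <- array(runif(6 * 24 * 24), c(6, 24, 24))
  p <- project_volume(a, c(35, 215), voxel_size = 1)
  flip <- p[2, , rev(seq_len(dim(p)[3]))]
  expect_equal(p[1, , ], flip, tolerance = 1e-10)
})

test_that("zero-distance propagation is pure Beer-Lambert absorption", {
  geom0 <- scan_geometry(distance_um = 0, detector_shape = c(32, 32))
  mat <- slab_material()
  p <- project_volume(mat, 0)
  i0 <- fresnel_propagate(p$delta[1, , ], p$beta[1, , ], geom0)
  lam <- geom0$wavelength_um
  expect_equal(i0, exp(-2 * (2 * pi / lam) * p$beta[1, , ]),
               tolerance = 1e-12)
})

test_that("pure-phase propagation conserves the mean intensity", {
  geom <- scan_geometry(distance_um = 50e4, detector_shape = c(32, 32))
  mat <- slab_material()
  p <- project_volume(mat, 0)
  for (zf in c(0.2, 1, 3)) {
    g <- geom; g$distance_um <- geom$distance_um * zf
    i1 <- fresnel_propagate(p$delta[1, , ], 0 * p$beta[1, , ], g)
    expect_equal(mean(i1), 1, tolerance = 1e-6)
  }
})

test_that("propagation reproduces the Fresnel integral by quadrature", {
  # localized 1D phase feature, constant along rows: the 2D propagator
  # acts as a 1D one
  n <- 128
  px <- 5.92
  lam <- energy_to_wavelength(20)
  z <- 50e4
  x <- (seq_len(n) - n / 2) * px
  phi_of <- function(s) 0.8 * exp(-s^2 / (2 * (2 * px)^2))
  pd <- -phi_of(x) * lam / (2 * pi)      # projected delta giving phase phi
  geom <- scan_geometry(distance_um = z, detector_shape = c(8, n))
  img <- matrix(rep(pd, each = 8), 8, n)
  got <- fresnel_propagate(img, 0 * img, geom)[4, ]

  # quadrature oracle: U0 = 1 + (U0 - 1) with the second term compactly
  # supported, so the Fresnel integral reduces to unity plus a finite
  # integral that can be sampled finely enough to resolve the chirp
  xs <- seq(-80, 80, by = 0.01)
  du <- exp(1i * phi_of(xs)) - 1
  core <- which(abs(x) <= 190)
  quad <- vapply(x[core], function(xi) {
    k <- exp(1i * pi * (xi - xs)^2 / (lam * z))
    Mod(1 + sum(du * k) * 0.01 / sqrt(1i * lam * z))^2
  }, numeric(1))
  rms <- sqrt(mean((got[core] - quad)^2)) / mean(quad)
  expect_lt(rms, 0.01)
})

test_that("a vessel boundary at 50 cm shows fringes absent at contact", {
  ph <- suppressWarnings(vascular_phantom(3, shape = c(32, 32, 32),
                                          n_levels = 0, root_radius = 30))
  p <- project_volume(ph$material, 0)
  gz <- desk_geometry(32, 1)
  g0 <- gz; g0$distance_um <- 0
  i_far <- fresnel_propagate(p$delta[1, , ], p$beta[1, , ], gz)
  i_0 <- fresnel_propagate(p$delta[1, , ], p$beta[1, , ], g0)
  # peak-to-trough contrast is strictly amplified by edge enhancement
  expect_gt(max(i_far) - min(i_far), 1.5 * (max(i_0) - min(i_0)))
  expect_gt(max(i_far), 1)   # bright fringe overshoots unit intensity
})

test_that("noiseless acquisition is exactly dark + flat * intensity", {
  ph <- suppressWarnings(vascular_phantom(5, shape = c(24, 24, 24),
                                          n_levels = 0, root_radius = 20))
  geom <- desk_geometry(24, 4)
  ps <- acquire(ph$material, geom, seed = 1, noise = FALSE)
  i_norm <- flat_dark_correct(ps)
  p <- project_volume(ph$material, scan_angles(geom))
  i_direct <- fresnel_propagate(p$delta[1, , ], p$beta[1, , ], geom)
  expect_equal(i_norm[1, , ], i_direct, tolerance = 1e-10)
})

test_that("acquisition with the same seed is bit-identical", {
  ph <- suppressWarnings(vascular_phantom(5, shape = c(24, 24, 24),
                                          n_levels = 0, root_radius = 20))
  geom <- desk_geometry(24, 3)
  a <- acquire(ph$material, geom, seed = 9, noise = TRUE)
  b <- acquire(ph$material, geom, seed = 9, noise = TRUE)
  expect_identical(a$frames, b$frames)
  c <- acquire(ph$material, geom, seed = 10, noise = TRUE)
  expect_false(identical(a$frames, c$frames))
})

test_that("flat/dark correction is invariant to a common gain", {
  ph <- suppressWarnings(vascular_phantom(5, shape = c(24, 24, 24),
                                          n_levels = 0, root_radius = 20))
  geom <- desk_geometry(24, 2)
  ps <- acquire(ph$material, geom, seed = 1, noise = FALSE)
  i1 <- flat_dark_correct(ps)
  ps2 <- ps
  ps2$frames <- ps$frames * 2.7
  ps2$flat <- ps$flat * 2.7
  ps2$dark <- ps$dark * 2.7
  i2 <- flat_dark_correct(ps2)
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("flat <= dark anywhere is a data error", {
  ph <- suppressWarnings(vascular_phantom(5, shape = c(16, 16, 16),
                                          n_levels = 0, root_radius = 12))
  geom <- desk_geometry(16, 1)
  ps <- acquire(ph$material, geom, seed = 1, noise = FALSE)
  ps$flat[3, 3] <- ps$dark[3, 3]
  expect_error(flat_dark_correct(ps), "flat must exceed dark")
})

test_that("Poisson noise is unbiased about the noiseless signal", {
  ph <- suppressWarnings(vascular_phantom(5, shape = c(16, 16, 16),
                                          n_levels = 0, root_radius = 12))
  geom <- desk_geometry(16, 1)
  clean <- flat_dark_correct(acquire(ph$material, geom, seed = 1,
                                     noise = FALSE))
  nrep <- 100
  acc <- 0
  for (s in seq_len(nrep))
    acc <- acc + flat_dark_correct(acquire(ph$material, geom, seed = s,
                                           photons_per_pixel = 1e4))
  m <- acc / nrep
  # per-pixel sd of the mean is ~sqrt(I/photons)/sqrt(N) ~ 1e-3; allow
  # the expected extreme over ~4k pixels plus the tiny 1/flat-hat bias
  expect_lt(max(abs(m - clean)), 0.01)
  expect_lt(abs(mean(m - clean)), 1e-3)
})

test_that("split acquisition overlaps by the requested rows", {
  ph <- suppressWarnings(vascular_phantom(5, shape = c(24, 24, 24),
                                          n_levels = 0, root_radius = 20))
  geom <- desk_geometry(24, 2)
  two <- acquire(ph$material, geom, seed = 1, noise = FALSE, split = TRUE,
                 overlap_px = 8)
  h <- dim(two$upper$frames)[2]
  expect_equal(h, ceiling((24 + 8) / 2))
  expect_equal(dim(two$lower$frames)[2], h)
  expect_equal(two$upper$half_id, "upper")
  expect_equal(two$lower$half_id, "lower")
  # overlapping rows carry identical content in noiseless mode
  iu <- flat_dark_correct(two$upper)
  il <- flat_dark_correct(two$lower)
  ov <- 2 * h - 24
  expect_equal(iu[1, (h - ov + 1):h, ], il[1, 1:ov, ], tolerance = 1e-10)
  expect_error(acquire(ph$material, geom, split = TRUE, overlap_px = 24),
               "overlap_px")
})
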