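test_that("FBP reconstructs an analytic uniform disc", {
  n <- 128
  sino <- disc_sinogram(n, 180, radius_um = 40, pixel_um = 1)
  ang <- seq(0, 180, length.out = 181)[1:180]
  rec <- fbp_reconstruct(sino, ang, 1)
  sl <- rec$data[1, , ]
  c0 <- (n - 1) / 2
  rr <- sqrt(outer(((0:(n - 1)) - c0)^2, ((0:(n - 1)) - c0)^2, "+"))
  truth <- ifelse(rr < 40, 1, 0)
  # RMSE below 5% of the disc contrast over the field of view
  fov <- rr < n / 2 - 2
  expect_lt(sqrt(mean((sl - truth)[fov]^2)), 0.05)
  # interior mean within 2% of the true density
  expect_equal(mean(sl[rr < 37]), 1, tolerance = 0.02)
})

test_that("zero sinogram reconstructs a zero slice", {
  sino <- array(0, c(60, 1, 32))
  ang <- seq(0, 180, length.out = 61)[1:60]
  rec <- fbp_reconstruct(sino, ang, 5.92)
  expect_equal(max(abs(rec$data)), 0)
})

test_that("FBP is linear", {
  set.seed(6)
  ang <- seq(0, 180, length.out = 41)[1:40]
  s1 <- array(rnorm(40 * 2 * 32), c(40, 2, 32))
  s2 <- array(rnorm(40 * 2 * 32), c(40, 2, 32))
  r1 <- fbp_reconstruct(s1, ang, 1)$data
  r2 <- fbp_reconstruct(s2, ang, 1)$data
  r12 <- fbp_reconstruct(2.5 * s1 - 1.5 * s2, ang, 1)$data
  expect_equal(r12, 2.5 * r1 - 1.5 * r2, tolerance = 1e-8)
})

test_that("re-projecting the reconstruction reproduces the sinogram", {
  n <- 128
  sino <- disc_sinogram(n, 180, radius_um = 40, pixel_um = 1)
  ang <- seq(0, 180, length.out = 181)[1:180]
  rec <- fbp_reconstruct(sino, ang, 1)
  rep2 <- reproject(rec, ang)
  rel <- sqrt(mean((rep2 - sino)^2)) / sqrt(mean(sino^2))
  expect_lt(rel, 0.05)
})

test_that("non-uniform angles are rejected", {
  sino <- array(1, c(4, 1, 16))
  expect_error(fbp_reconstruct(sino, c(0, 40, 90, 135), 1),
               "uniformly spaced")
})

test_that("grey rescale maps the percentile window onto 0..255", {
  set.seed(7)
  v <- voxel_volume(array(rnorm(20^3), c(20, 20, 20)), 1, "grey_float")
  g <- rescale_grey8(v, 0, 100)
  expect_equal(min(g$data), 0L)
  expect_equal(max(g$data), 255L)
  expect_true(all(g$data >= 0 & g$data <= 255))
  # monotone: ordering of voxels is preserved
  o <- order(v$data)
  expect_true(all(diff(g$data[o]) >= 0))
  # the mapping parameters are recorded for invertibility
  rs <- attr(g, "rescale")
  expect_equal(unname(rs), range(v$data))
})

test_that("grey rescale truncates at the requested percentiles", {
  v <- voxel_volume(array(seq(0, 1, length.out = 1000), c(10, 10, 10)),
                    1, "grey_float")
  g <- rescale_grey8(v, 10, 90)
  expect_gt(mean(g$data == 0), 0.08)   # bottom decile clipped to 0
  expect_gt(mean(g$data == 255), 0.08) # top decile clipped to 255
  expect_true(all(g$data >= 0 & g$data <= 255))
})

test_that("constant volumes rescale to zeros with a warning", {
  v <- voxel_volume(array(3.7, c(5, 5, 5)), 1, "grey_float")
  expect_warning(g <- rescale_grey8(v), "degenerate")
  expect_equal(unique(as.vector(g$data)), 0L)
})

test_that("phase correlation recovers exact integer shifts", {
  set.seed(8)
  a <- array(rnorm(40 * 24 * 24), c(40, 24, 24))
  for (s in list(c(0, 0, 0), c(9, 2, -3), c(21, -5, 4))) {
    b <- array(0, dim(a))
    for (z in 1:40) for (y in 1:24) for (x in 1:24) {
      zz <- z + s[1]; yy <- y + s[2]; xx <- x + s[3]
      if (zz >= 1 && zz <= 40 && yy >= 1 && yy <= 24 && xx >= 1 && xx <= 24)
        b[z, y, x] <- a[zz, yy, xx]
    }
    r <- find_shift_fft(a, b)
    expect_equal(r$shift, as.integer(s))
    expect_true(r$reliable)
  }
})

test_that("shift recovery survives Poisson noise at 100 photons", {
  set.seed(9)
  base <- array(0, c(32, 24, 24))
  # structured content: a few seeded blobs
  for (k in 1:8) {
    c0 <- c(sample(6:26, 1), sample(4:20, 1), sample(4:20, 1))
    base[c0[1] + (-2:2), c0[2] + (-2:2), c0[3] + (-2:2)] <-
      base[c0[1] + (-2:2), c0[2] + (-2:2), c0[3] + (-2:2)] + 1
  }
  s <- c(7, 3, -2)
  shifted <- array(0, dim(base))
  for (z in 1:32) for (y in 1:24) for (x in 1:24) {
    zz <- z + s[1]; yy <- y + s[2]; xx <- x + s[3]
    if (zz >= 1 && zz <= 32 && yy >= 1 && yy <= 24 && xx >= 1 && xx <= 24)
      shifted[z, y, x] <- base[zz, yy, xx]
  }
  hits <- 0
  for (rep in 1:20) {
    na <- array(rpois(length(base), 100 * (0.5 + base)) / 100,
                dim(base))
    nb <- array(rpois(length(base), 100 * (0.5 + shifted)) / 100,
                dim(base))
    r <- find_shift_fft(na, nb)
    if (all(r$shift == s)) hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("degenerate constant stacks are flagged unreliable", {
  a <- array(1, c(8, 8, 8))
  expect_warning(r <- find_shift_fft(a, a), "unreliable")
  expect_false(r$reliable)
})

test_that("merging halves obeys the slice-count contract", {
  set.seed(10)
  up <- array(rnorm(30 * 8 * 8), c(30, 8, 8))
  lo <- array(rnorm(25 * 8 * 8), c(25, 8, 8))
  m0 <- merge_halves(up, lo, c(30, 0, 0), voxel_size = 1)   # overlap 0
  expect_equal(dim(m0$data)[1], 55)
  m6 <- merge_halves(up, lo, c(24, 0, 0), voxel_size = 1)   # overlap 6
  expect_equal(dim(m6$data)[1], 49)
  # two 963-slice halves at 200 overlap give 1726 slices
  u2 <- array(0, c(963, 2, 2)); l2 <- array(0, c(963, 2, 2))
  expect_equal(dim(merge_halves(u2, l2, c(763, 0, 0),
                                voxel_size = 1)$data)[1], 1726)
  expect_error(merge_halves(up, lo, c(33, 0, 0), voxel_size = 1), "gap of 3")
})

test_that("stitched phantom halves are continuous across the seam", {
  ph <- suppressWarnings(vascular_phantom(2, shape = c(48, 48, 48),
                                          n_levels = 2, root_radius = 20))
  geom <- desk_geometry(48, 40)
  two <- acquire(ph$material, geom, seed = 2, split = TRUE,
                 overlap_px = 12, photons_per_pixel = 1e4)
  rp <- retrieval_params(400, geometry = geom, beta = 1)
  rec_half <- function(ps)
    fbp_reconstruct(-log(tie_hom_filter(flat_dark_correct(ps), rp)),
                    ps$angles_deg, geom$pixel_size_um)
  ru <- rec_half(two$upper)
  rl <- rec_half(two$lower)
  sh <- find_shift_fft(ru, rl)
  expect_equal(sh$shift[1], 48L - dim(ru$data)[1])  # lower half's start slice
  mg <- merge_halves(ru, rl, sh$shift, cross_fade = TRUE)
  expect_equal(dim(mg$data)[1], 48)
  # seam jump no worse than twice the typical inter-slice difference
  seam <- dim(ru$data)[1]
  jump <- mean(abs(mg$data[seam + 1, , ] - mg$data[seam, , ]))
  typical <- mean(abs(mg$data[-1, , ] - mg$data[-48, , ]))
  expect_lt(jump, 2 * typical)
})
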