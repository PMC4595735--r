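test_that("a straight cylinder thins to a single centred path", {
  cyl <- cylinder_mask(13, 13, 70, x0 = 6, x1 = 65, cy = 7, cz = 7, r = 4)
  sk <- skeletonize(cyl)
  g <- build_graph(sk, distance_map(cyl), prune_spurs_below = 0)
  expect_equal(nrow(g$segments), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2L)
  expect_equal(sum(g$nodes$kind == "junction"), 0L)
  # the skeleton lies on the cylinder axis
  w <- which(sk$data == 1L, arr.ind = TRUE)
  expect_true(all(w[, 1] == 7 & w[, 2] == 7))
  # thinning retracts the line by about one radius per end
  expect_gte(g$segments$length_um, 60 - 2 * 4 - 2)
  expect_lte(g$segments$length_um, 60)
})

test_that("thinning preserves connected components over a seed battery", {
  for (s in 1:10) {
    set.seed(s)
    m <- array(0L, c(24, 24, 24))
    for (k in 1:4) {
      c0 <- sample(5:19, 3, replace = TRUE)
      m[c0[1] + (-2:2), c0[2] + (-2:2), c0[3] + (-2:2)] <- 1L
    }
    mv <- voxel_volume(m, 1, "mask")
    sk <- skeletonize(mv)
    expect_equal(count_components(sk), count_components(mv))
  }
})

test_that("a solid torus skeletonizes to exactly one cycle", {
  n <- 25
  m <- array(0L, c(7, n, n))
  for (x in 1:n) for (y in 1:n) for (z in 1:7) {
    rr <- sqrt((x - 13)^2 + (y - 13)^2)
    if ((rr - 7)^2 + (z - 4)^2 <= 4.5) m[z, y, x] <- 1L
  }
  mv <- voxel_volume(m, 1, "mask")
  sk <- skeletonize(mv)
  g <- build_graph(sk, distance_map(mv), prune_spurs_below = 0)
  expect_equal(nrow(g$segments), 1L)
  expect_equal(nrow(g$nodes), 0L)       # no endpoints, no junctions
  expect_equal(g$n_components, 1L)
  # cycle count via the Euler relation: segments - nodes + components
  expect_equal(nrow(g$segments) - nrow(g$nodes) + 0L, g$n_components)
})

test_that("distance map gives exact unit distances and cylinder radii", {
  m <- array(0L, c(7, 7, 7)); m[4, 4, 4] <- 1L
  dm <- distance_map(voxel_volume(m, 5.92, "mask"))
  expect_equal(dm$data[4, 4, 4], 5.92)
  expect_equal(dm$data[1, 1, 1], 0)

  cyl <- cylinder_mask(13, 13, 40, 3, 38, 7, 7, r = 4, voxel_size = 1)
  dm2 <- distance_map(cyl)
  centre <- dm2$data[7, 7, 10:30]
  expect_true(all(abs(centre - 4) <= 0.5))

  # the complement's distance map vanishes exactly on the original
  # foreground and is positive elsewhere
  inv <- voxel_volume(array(1L - cyl$data, dim(cyl$data)), 1, "mask")
  dmc <- distance_map(inv)
  expect_true(all(dmc$data[cyl$data == 1] == 0))
  expect_true(all(dmc$data[cyl$data == 0] > 0))
})

test_that("a drawn Y-skeleton yields one junction and three segments", {
  m <- array(0L, c(3, 30, 30))
  for (i in 0:14) m[2, 15, 3 + i] <- 1L
  for (i in 1:10) {
    m[2, 15 - i, 17 + i] <- 1L
    m[2, 15 + i, 17 + i] <- 1L
  }
  mv <- voxel_volume(m, 1, "mask")
  g <- build_graph(mv, distance_map(mv), prune_spurs_below = 0)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3L)
  expect_equal(nrow(g$segments), 3L)
})

test_that("a diagonal path measures sqrt(3) per step", {
  m <- array(0L, c(12, 12, 12))
  for (i in 1:10) m[i, i, i] <- 1L
  mv <- voxel_volume(m, 2, "mask")
  g <- build_graph(mv, distance_map(mv), prune_spurs_below = 0)
  expect_equal(nrow(g$segments), 1L)
  expect_equal(g$segments$length_um, 9 * sqrt(3) * 2, tolerance = 1e-12)
})

test_that("phantom trees recover the oracle's bifurcation/segment counts", {
  for (s in c(1, 2, 3)) {
    ph <- suppressWarnings(vascular_phantom(s))
    g <- suppressMessages(build_graph(skeletonize(ph$vessel_mask),
                                      distance_map(ph$vessel_mask)))
    o <- tree_oracle(ph$tree)
    expect_equal(sum(g$nodes$kind == "junction"), o$n_branch)
    expect_equal(nrow(g$segments), o$n_segments)
    # Euler relation on the acyclic network
    expect_equal(nrow(g$segments),
                 sum(g$nodes$kind == "junction") +
                   sum(g$nodes$kind == "endpoint") - g$n_components)
  }
})

test_that("metrics follow their definitions on a known cylinder", {
  vsz <- 5.92
  cyl <- cylinder_mask(32, 32, 70, 6, 65, 16, 16, r = 5, voxel_size = vsz)
  sk <- skeletonize(cyl)
  g <- build_graph(sk, distance_map(cyl))
  sample_mask <- voxel_volume(array(1L, dim(cyl$data)), vsz, "mask")
  met <- compute_metrics(g, cyl, sample_mask)
  expect_equal(met$n_bifurcations, 0L)
  expect_equal(met$n_segments, 1L)
  expect_equal(met$vessel_volume_um3, sum(cyl$data) * vsz^3)
  expect_equal(met$vessel_volume_fraction,
               sum(cyl$data) / length(cyl$data))
  # diameter within one voxel of the true 2r
  expect_lt(abs(met$diameter_histogram$fraction %*%
                  rep(1, 16) - 1), 1e-9)
  d_est <- g$segments$mean_diameter_um
  expect_lt(abs(d_est - 2 * 5 * vsz), vsz)
  # full-mask sample: volume fraction is one
  met2 <- compute_metrics(g, sample_mask, sample_mask)
  expect_equal(met2$vessel_volume_fraction, 1)
})

test_that("histogram fractions sum to one and split at 30 um", {
  ph <- suppressWarnings(vascular_phantom(4))
  g <- suppressMessages(build_graph(skeletonize(ph$vessel_mask),
                                    distance_map(ph$vessel_mask)))
  met <- compute_metrics(g, ph$vessel_mask, ph$parenchyma_mask)
  expect_equal(sum(met$diameter_histogram$fraction), 1, tolerance = 1e-9)
  manual <- mean(g$segments$mean_diameter_um < 30)
  expect_equal(met$fraction_below_30um, manual)
  # length-weighted variant also normalizes
  metw <- compute_metrics(g, ph$vessel_mask, ph$parenchyma_mask,
                          weight = "length")
  expect_equal(sum(metw$diameter_histogram$fraction), 1, tolerance = 1e-9)
})

test_that("metrics are invariant to axis permutation of the mask", {
  ph <- suppressWarnings(vascular_phantom(5, shape = c(48, 48, 48),
                                          n_levels = 2, root_radius = 20))
  m <- ph$vessel_mask
  g1 <- suppressMessages(build_graph(skeletonize(m), distance_map(m)))
  met1 <- compute_metrics(g1, m, ph$parenchyma_mask)
  mp <- voxel_volume(aperm(m$data, c(3, 1, 2)), m$voxel_size, "mask")
  pp <- voxel_volume(aperm(ph$parenchyma_mask$data, c(3, 1, 2)),
                     m$voxel_size, "mask")
  g2 <- suppressMessages(build_graph(skeletonize(mp), distance_map(mp)))
  met2 <- compute_metrics(g2, mp, pp)
  expect_equal(met1$n_bifurcations, met2$n_bifurcations)
  expect_equal(met1$n_segments, met2$n_segments)
  expect_equal(met1$vessel_volume_fraction, met2$vessel_volume_fraction)
  # thinning visits the six directions in a fixed order, so the skeleton
  # (and with it the exact length) shifts slightly under permutation
  expect_equal(met1$total_length_um, met2$total_length_um, tolerance = 0.1)
})

test_that("volume fraction is monotone under dilation", {
  ph <- suppressWarnings(vascular_phantom(6, shape = c(40, 40, 40),
                                          n_levels = 1, root_radius = 16))
  m <- ph$vessel_mask
  g <- suppressMessages(build_graph(skeletonize(m), distance_map(m)))
  f1 <- compute_metrics(g, m, ph$parenchyma_mask)$vessel_volume_fraction
  # dilate by one voxel through the complement's distance transform
  dil <- distance_map(voxel_volume(1L - m$data, 1, "mask"),
                      voxel_size = 1)$data <= 1
  md <- voxel_volume(array(as.integer(dil | m$data == 1), dim(m$data)),
                     m$voxel_size, "mask")
  f2 <- compute_metrics(g, md, ph$parenchyma_mask)$vessel_volume_fraction
  expect_gte(f2, f1)
})

test_that("empty masks degrade gracefully", {
  m <- voxel_volume(array(0L, c(8, 8, 8)), 1, "mask")
  expect_warning(sk <- skeletonize(m), "empty")
  g <- build_graph(sk, distance_map(m))
  expect_equal(nrow(g$segments), 0L)
  expect_warning(met <- compute_metrics(g, m, m), "empty graph")
  expect_equal(met$n_bifurcations, 0L)
  expect_equal(met$total_length_um, 0)
})

test_that("recovery report is exact on the identity comparison", {
  ph <- suppressWarnings(vascular_phantom(7, shape = c(64, 64, 64),
                                          n_levels = 2, root_radius = 22))
  g <- suppressMessages(build_graph(skeletonize(ph$vessel_mask),
                                    distance_map(ph$vessel_mask)))
  rep1 <- diameter_recovery_report(g, ph$tree)
  expect_equal(rep1$unmatched_fraction, 0)
  expect_false(rep1$flagged)
  # noiseless voxelized tree: diameter RMSE within one voxel
  expect_lte(rep1$diameter_rmse_um, 5.92)
})
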