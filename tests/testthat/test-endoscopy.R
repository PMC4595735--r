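straight_tube <- function() {
  cyl <- cylinder_mask(13, 13, 60, 4, 57, 7, 7, r = 4, voxel_size = 5.92)
  sk <- skeletonize(cyl)
  g <- build_graph(sk, distance_map(cyl), prune_spurs_below = 0)
  list(mask = cyl, graph = g, dm = distance_map(cyl))
}

test_that("a straight tube plans a straight path of the right length", {
  tube <- straight_tube()
  eps <- tube$graph$nodes[tube$graph$nodes$kind == "endpoint", ]
  p1 <- unlist(eps[1, c("x", "y", "z")]) * 5.92
  p2 <- unlist(eps[2, c("x", "y", "z")]) * 5.92
  pth <- plan_path(tube$graph, p1, p2)
  chord <- sqrt(sum((p2 - p1)^2))
  expect_lt(abs(attr(pth, "length_um") - chord), 5.92)
  # consecutive positions strictly advance
  expect_true(all(rowSums(diff(pth)^2) > 0))
})

test_that("a Y network traverses its junction exactly once", {
  m <- array(0L, c(3, 30, 30))
  for (i in 0:14) m[2, 15, 3 + i] <- 1L
  for (i in 1:10) {
    m[2, 15 - i, 17 + i] <- 1L
    m[2, 15 + i, 17 + i] <- 1L
  }
  mv <- voxel_volume(m, 1, "mask")
  g <- build_graph(mv, distance_map(mv), prune_spurs_below = 0)
  jc <- g$nodes[g$nodes$kind == "junction", ]
  tips <- g$nodes[g$nodes$kind == "endpoint", ]
  # trunk tip to a branch tip
  trunk_tip <- tips[which.min(tips$x), ]
  branch_tip <- tips[which.max(tips$y), ]
  pth <- plan_path(g, unlist(trunk_tip[c("x", "y", "z")]),
                   unlist(branch_tip[c("x", "y", "z")]))
  near_j <- rowSums(sweep(pth, 2,
                          unlist(jc[c("x", "y", "z")]))^2) < 1.5^2
  # the junction neighbourhood is entered once (one contiguous run)
  runs <- rle(near_j)$values
  expect_equal(sum(runs), 1L)
})

test_that("planned length matches exhaustive enumeration on a phantom", {
  ph <- suppressWarnings(vascular_phantom(9))
  g <- suppressMessages(build_graph(skeletonize(ph$vessel_mask),
                                    distance_map(ph$vessel_mask)))
  eps <- which(g$nodes$kind == "endpoint")
  pairs <- list(c(1, 4), c(2, 7), c(3, 5))
  for (pr in pairs) {
    a <- eps[pr[1]]; b <- eps[pr[2]]
    oracle <- enumerate_shortest(g, a, b)
    pth <- plan_path(g, a, b)
    # concatenated voxel path may hop across junction clusters, so allow
    # a few voxel diagonals of slack relative to the graph metric
    expect_lt(abs(attr(pth, "length_um") - oracle),
              4 * sqrt(3) * g$voxel_size)
  }
})

test_that("path planning is symmetric", {
  tube <- straight_tube()
  eps <- tube$graph$nodes[tube$graph$nodes$kind == "endpoint", ]
  p1 <- unlist(eps[1, c("x", "y", "z")]) * 5.92
  p2 <- unlist(eps[2, c("x", "y", "z")]) * 5.92
  f <- plan_path(tube$graph, p1, p2)
  b <- plan_path(tube$graph, p2, p1)
  expect_equal(f, b[rev(seq_len(nrow(b))), ], ignore_attr = TRUE)
})

test_that("disconnected endpoints raise a no-path error", {
  m <- array(0L, c(3, 10, 30))
  m[2, 5, 2:12] <- 1L
  m[2, 5, 18:28] <- 1L
  mv <- voxel_volume(m, 1, "mask")
  g <- build_graph(mv, distance_map(mv), prune_spurs_below = 0)
  expect_error(plan_path(g, c(3, 4, 1), c(26, 4, 1)),
               "different connected components")
})

test_that("camera poses stay inside the lumen with orthonormal frames", {
  tube <- straight_tube()
  eps <- tube$graph$nodes[tube$graph$nodes$kind == "endpoint", ]
  pth <- plan_path(tube$graph,
                   unlist(eps[1, c("x", "y", "z")]) * 5.92,
                   unlist(eps[2, c("x", "y", "z")]) * 5.92)
  cam <- camera_poses(pth, tube$dm)
  expect_equal(nrow(cam), nrow(pth))
  expect_true(all(cam$lumen_um > 0))
  # forward/up orthonormal
  expect_lt(max(abs(rowSums(cam[, c("fx", "fy", "fz")] *
                              cam[, c("ux", "uy", "uz")]))), 1e-9)
  expect_equal(unname(rowSums(cam[, c("ux", "uy", "uz")]^2)),
               rep(1, nrow(cam)), tolerance = 1e-9)
  # a straight path keeps constant forward and up
  expect_lt(max(apply(cam[, c("fx", "fy", "fz")], 2, stats::sd)), 1e-9)
  expect_lt(max(apply(cam[, c("ux", "uy", "uz")], 2, stats::sd)), 1e-9)
})

test_that("up vectors are rotation-minimizing on branching phantom paths", {
  ph <- suppressWarnings(vascular_phantom(10, shape = c(64, 64, 64),
                                          n_levels = 2, root_radius = 22))
  g <- suppressMessages(build_graph(skeletonize(ph$vessel_mask),
                                    distance_map(ph$vessel_mask)))
  dm <- distance_map(ph$vessel_mask)
  eps <- which(g$nodes$kind == "endpoint")
  for (pr in list(c(1, 2), c(2, 3), c(1, 4))) {
    pth <- plan_path(g, eps[pr[1]], eps[pr[2]])
    cam <- suppressMessages(camera_poses(pth, dm))
    expect_true(all(cam$lumen_um > 0))
    f <- as.matrix(cam[, c("fx", "fy", "fz")])
    u <- as.matrix(cam[, c("ux", "uy", "uz")])
    ang_u <- acos(pmin(1, rowSums(u[-1, ] * u[-nrow(u), ])))
    ang_f <- acos(pmin(1, rowSums(f[-1, ] * f[-nrow(f), ])))
    # parallel transport: up never rotates more than the tangent (plus
    # numerical slack) -- no spinning about the view axis
    expect_true(all(ang_u <= ang_f + 0.02))
  }
})

test_that("surface meshes are watertight with correct topology", {
  # single voxel -> topological sphere
  m1 <- voxel_volume(array(1L, c(1, 1, 1)), 1, "mask")
  mesh1 <- export_surface(m1)
  expect_equal(mesh_euler_characteristic(mesh1), 2L)
  expect_equal(euler_oracle(mesh1), 2L)

  # digital ball: enclosed volume within 5% of the voxel count
  n <- 19
  b <- array(0L, c(n, n, n))
  for (x in 1:n) for (y in 1:n) for (z in 1:n)
    if ((x - 10)^2 + (y - 10)^2 + (z - 10)^2 <= 49) b[z, y, x] <- 1L
  mb <- voxel_volume(b, 5.92, "mask")
  mesh2 <- export_surface(mb)
  expect_equal(mesh_euler_characteristic(mesh2), 2L)
  expect_lt(abs(mesh_volume(mesh2) - sum(b) * 5.92^3) / (sum(b) * 5.92^3),
            0.05)

  # solid torus -> Euler characteristic zero
  t <- array(0L, c(7, 25, 25))
  for (x in 1:25) for (y in 1:25) for (z in 1:7) {
    rr <- sqrt((x - 13)^2 + (y - 13)^2)
    if ((rr - 7)^2 + (z - 4)^2 <= 4.5) t[z, y, x] <- 1L
  }
  mesh3 <- export_surface(voxel_volume(t, 1, "mask"))
  expect_equal(mesh_euler_characteristic(mesh3), 0L)
  expect_error(export_surface(voxel_volume(array(0L, c(3, 3, 3)), 1,
                                           "mask")), "empty mask")
})

test_that("mesh and path writers emit readable files", {
  tube <- straight_tube()
  mesh <- export_surface(tube$mask)
  d <- withr::local_tempdir()
  write_ply(mesh, file.path(d, "m.ply"))
  write_vrml(mesh, file.path(d, "m.wrl"))
  ply <- readLines(file.path(d, "m.ply"))
  expect_equal(ply[1], "ply")
  expect_true(any(grepl(sprintf("element vertex %d", nrow(mesh$vertices)),
                        ply)))
  expect_equal(readLines(file.path(d, "m.wrl"))[1], "#VRML V2.0 utf8")

  eps <- tube$graph$nodes[tube$graph$nodes$kind == "endpoint", ]
  pth <- plan_path(tube$graph, unlist(eps[1, c("x", "y", "z")]) * 5.92,
                   unlist(eps[2, c("x", "y", "z")]) * 5.92)
  cam <- camera_poses(pth, tube$dm)
  write_path_csv(cam, file.path(d, "path.csv"))
  back <- read.csv(file.path(d, "path.csv"))
  expect_equal(nrow(back), nrow(cam))
  expect_equal(back$x_um, cam$x)
})
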