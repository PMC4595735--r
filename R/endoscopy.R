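# Virtual micro-endoscopy: shortest-path planning along the centerline
# graph, rotation-minimizing camera poses, and surface-mesh export.

# nearest skeleton voxel (graph path voxel) to a point given in um (x,y,z)
nearest_on_graph <- function(graph, point_um) {
  vs <- graph$voxel_size
  best <- NULL; best_d <- Inf
  for (i in seq_along(graph$paths)) {
    p <- graph$paths[[i]]
    d2 <- (p[, 3] * vs - point_um[1])^2 + (p[, 2] * vs - point_um[2])^2 +
      (p[, 1] * vs - point_um[3])^2
    j <- which.min(d2)
    if (d2[j] < best_d) { best_d <- d2[j]; best <- list(seg = i, at = j) }
  }
  best
}

# igraph over the skeleton graph: vertices = node ids plus two optional
# split points; returns list(g, vertex names of start/end)
segment_igraph <- function(graph, start, end) {
  segs <- graph$segments
  vs <- graph$voxel_size
  vmax <- nrow(graph$nodes)
  edges <- character(0); weights <- numeric(0); eseg <- integer(0)
  epart <- list()
  add <- function(a, b, w, seg, rng) {
    edges <<- c(edges, as.character(a), as.character(b))
    weights <<- c(weights, w)
    eseg <<- c(eseg, seg)
    epart[[length(eseg)]] <<- rng
  }
  splits <- list(start = start, end = end)
  for (i in seq_len(nrow(segs))) {
    if (is.na(segs$node_a[i]) || is.na(segs$node_b[i])) next
    cuts <- integer(0)
    for (nm in names(splits)) {
      s <- splits[[nm]]
      if (!is.null(s) && s$seg == i) cuts <- c(cuts, s$at)
    }
    p <- graph$paths[[i]]
    np <- nrow(p)
    bnd <- sort(unique(c(1L, cuts, np)))
    plen <- function(rng) {
      if (length(rng) < 2) return(0)
      sum(sqrt(rowSums((p[rng[-1], , drop = FALSE] -
                          p[rng[-length(rng)], , drop = FALSE])^2))) * vs
    }
    vertex_at <- function(j) {
      if (j == 1L) as.character(segs$node_a[i])
      else if (j == np) as.character(segs$node_b[i])
      else sprintf("s%d@%d", i, j)
    }
    for (k in seq_len(length(bnd) - 1)) {
      rng <- bnd[k]:bnd[k + 1]
      add(vertex_at(bnd[k]), vertex_at(bnd[k + 1]), plen(rng), i, rng)
    }
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  igraph::E(g)$seg <- eseg
  igraph::E(g)$part <- seq_along(eseg)
  list(g = g, parts = epart,
       vstart = if (!is.null(start)) {
         p <- graph$paths[[start$seg]]
         vertex_at_of(graph, start, p)
       } else NULL,
       vend = if (!is.null(end)) {
         p <- graph$paths[[end$seg]]
         vertex_at_of(graph, end, p)
       } else NULL)
}

vertex_at_of <- function(graph, s, p) {
  segs <- graph$segments
  np <- nrow(p)
  if (s$at == 1L) as.character(segs$node_a[s$seg])
  else if (s$at == np) as.character(segs$node_b[s$seg])
  else sprintf("s%d@%d", s$seg, s$at)
}

#' Plan a fly-through path between two points of the vessel network
#'
#' Maps `start` and `end` to their nearest centerline voxels, finds the
#' shortest path through the centerline graph by segment length (segments
#' are split at the entry points when they fall mid-segment), and
#' concatenates the segment voxel paths into one ordered centerline point
#' list in micrometers.
#'
#' @param graph a [build_graph()] result.
#' @param start,end numeric `c(x, y, z)` positions in micrometers (or a
#'   graph node id given as a single integer).
#' @return Matrix of path points (columns `x, y, z`, micrometers) with
#'   attribute `length_um`; the path is unsmoothed (smoothing belongs to
#'   [camera_poses()]).
#' @export
plan_path <- function(graph, start, end) {
  stopifnot(inherits(graph, "skeleton_graph"))
  vs <- graph$voxel_size
  as_anchor <- function(p) {
    if (length(p) == 1L) {
      # a node id: locate it on an incident segment
      segs <- graph$segments
      i <- which(segs$node_a == p | segs$node_b == p)[1]
      if (is.na(i)) stop("node has no incident segment")
      at <- if (!is.na(segs$node_a[i]) && segs$node_a[i] == p) 1L
        else nrow(graph$paths[[i]])
      list(seg = i, at = at)
    } else nearest_on_graph(graph, p)
  }
  sa <- as_anchor(start)
  se <- as_anchor(end)
  sg <- segment_igraph(graph, sa, se)
  if (!sg$vstart %in% igraph::V(sg$g)$name ||
      !sg$vend %in% igraph::V(sg$g)$name)
    stop("start or end does not map onto the centerline graph")
  comp <- igraph::components(sg$g)
  ms <- comp$membership[sg$vstart]; me <- comp$membership[sg$vend]
  if (ms != me)
    stop(sprintf(paste0("start and end lie in different connected ",
                        "components (%d vs %d): no path"), ms, me))
  sp <- igraph::shortest_paths(sg$g, sg$vstart, sg$vend,
                               output = "epath")$epath[[1]]
  if (length(sp) == 0L && sg$vstart != sg$vend)
    stop("no path between start and end")
  pts <- NULL
  anchor <- graph$paths[[sa$seg]][sa$at, ]  # start voxel (z, y, x)
  for (eid in as.integer(sp)) {
    part <- sg$parts[[igraph::E(sg$g)$part[eid]]]
    seg <- igraph::E(sg$g)$seg[eid]
    p <- graph$paths[[seg]][part, , drop = FALSE]
    # orient geometrically: the nearer end continues the path so far
    ref <- if (is.null(pts)) anchor else pts[nrow(pts), ]
    if (sum((p[1, ] - ref)^2) > sum((p[nrow(p), ] - ref)^2))
      p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    if (is.null(pts)) pts <- p
    else {
      if (all(pts[nrow(pts), ] == p[1, ])) p <- p[-1, , drop = FALSE]
      pts <- rbind(pts, p)
    }
  }
  if (is.null(pts)) pts <- graph$paths[[sa$seg]][sa$at, , drop = FALSE]
  out <- cbind(x = pts[, 3] * vs, y = pts[, 2] * vs, z = pts[, 1] * vs)
  attr(out, "length_um") <-
    sum(sqrt(rowSums((out[-1, , drop = FALSE] -
                        out[-nrow(out), , drop = FALSE])^2)))
  out
}

# moving-average smoothing preserving the endpoints
smooth_path <- function(path, w) {
  n <- nrow(path)
  if (w <= 1 || n <= 2) return(path)
  half <- floor(w / 2)
  out <- path
  for (i in 2:(n - 1)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(path[lo:hi, , drop = FALSE])
  }
  out
}

#' Camera poses along a fly-through path
#'
#' Smooths the centerline path with a moving average (endpoints pinned),
#' sets the camera forward vector to the normalized local tangent, and
#' propagates the up vector by parallel transport (the double-reflection
#' rotation-minimizing frame), so the camera does not spin about its axis.
#' Every pose must lie strictly inside the lumen (positive distance-map
#' value at its voxel); if smoothing pushes a pose into the wall the
#' window is reduced automatically (with a message) until all poses are
#' inside.
#'
#' @param path matrix from [plan_path()] (columns x/y/z, micrometers).
#' @param distance a [distance_map()] of the vessel mask.
#' @param smooth_window moving-average window in path points.
#' @param frame_rate_hint poses per second stored on the result.
#' @return Object of class `camera_path`: data.frame with `x, y, z`
#'   (micrometers), forward `fx, fy, fz`, up `ux, uy, uz`, and lumen
#'   radius `lumen_um` at each pose.
#' @export
camera_poses <- function(path, distance, smooth_window = 5,
                         frame_rate_hint = 25) {
  stopifnot(is.matrix(path), nrow(path) >= 2)
  dmap <- as_vol_array(distance)
  vs <- if (inherits(distance, "voxel_volume")) distance$voxel_size else
    stop("`distance` must be a distance_map() result")
  lumen_at <- function(p) {
    idx <- round(p[, c(3, 2, 1), drop = FALSE] / vs) + 1L
    idx[, 1] <- pmin(pmax(idx[, 1], 1L), dim(dmap)[1])
    idx[, 2] <- pmin(pmax(idx[, 2], 1L), dim(dmap)[2])
    idx[, 3] <- pmin(pmax(idx[, 3], 1L), dim(dmap)[3])
    dmap[idx]
  }
  w <- smooth_window
  repeat {
    sp <- smooth_path(path, w)
    lum <- lumen_at(sp)
    if (all(lum > 0) || w <= 1) break
    w <- w - 2
    message(sprintf("smoothing pushed a pose outside the lumen; window -> %d",
                    max(w, 1)))
  }
  n <- nrow(sp)
  fwd <- matrix(0, n, 3)
  fwd[1, ] <- sp[2, ] - sp[1, ]
  fwd[n, ] <- sp[n, ] - sp[n - 1, ]
  if (n > 2) fwd[2:(n - 1), ] <- sp[3:n, ] - sp[1:(n - 2), ]
  nrm <- sqrt(rowSums(fwd^2))
  nrm[nrm == 0] <- 1
  fwd <- fwd / nrm

  up <- matrix(0, n, 3)
  a0 <- if (abs(fwd[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- a0 - sum(a0 * fwd[1, ]) * fwd[1, ]
  up[1, ] <- u / sqrt(sum(u^2))
  for (i in 2:n) {
    # double-reflection rotation-minimizing frame propagation
    v1 <- sp[i, ] - sp[i - 1, ]
    c1 <- sum(v1^2)
    if (c1 < 1e-20) { up[i, ] <- up[i - 1, ]; next }
    uL <- up[i - 1, ] - (2 / c1) * sum(v1 * up[i - 1, ]) * v1
    tL <- fwd[i - 1, ] - (2 / c1) * sum(v1 * fwd[i - 1, ]) * v1
    v2 <- fwd[i, ] - tL
    c2 <- sum(v2^2)
    u <- if (c2 < 1e-20) uL else uL - (2 / c2) * sum(v2 * uL) * v2
    u <- u - sum(u * fwd[i, ]) * fwd[i, ]
    up[i, ] <- u / sqrt(sum(u^2))
  }
  structure(data.frame(
    x = sp[, 1], y = sp[, 2], z = sp[, 3],
    fx = fwd[, 1], fy = fwd[, 2], fz = fwd[, 3],
    ux = up[, 1], uy = up[, 2], uz = up[, 3],
    lumen_um = lumen_at(sp)
  ), class = c("camera_path", "data.frame"),
  frame_rate_hint = frame_rate_hint, smooth_window = w)
}

#' Extract a surface mesh of a binary mask
#'
#' Iso-surface at level 0.5 by marching cubes in its tetrahedral
#' decomposition (each grid cell is split into six tetrahedra around the
#' main diagonal; the split is translation-invariant, so the mesh is
#' watertight for components away from the volume border -- the field is
#' zero-padded so border-touching components are closed too).  Vertices
#' are emitted in micrometers, de-duplicated, with outward-pointing
#' triangle winding.
#'
#' @param mask binary [voxel_volume()] (non-empty).
#' @param voxel_size for bare-array input.
#' @return Object of class `tri_mesh`: `vertices` (n x 3, micrometers,
#'   columns x/y/z) and `faces` (m x 3, 1-based vertex indices).
#' @export
export_surface <- function(mask, voxel_size = NULL) {
  m <- as_mask_array(mask)
  vs <- vol_voxel_size(mask, voxel_size)
  if (sum(m) == 0L) stop("empty mask: no surface")
  d <- dim(m)
  f <- array(0, d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  res <- cpp_march_tets(f, dim(f), 0.5)
  v <- res$vertices
  # cpp coordinates are (x, y, z) in padded voxel units -> shift and scale
  verts <- cbind(x = (v[, 3] - 1) * vs, y = (v[, 2] - 1) * vs,
                 z = (v[, 1] - 1) * vs)
  structure(list(vertices = verts, faces = res$faces + 1L),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Euler characteristic of a triangle mesh
#'
#' `V - E + F` with edges counted once; 2 for a topological sphere, 0 for
#' a torus.
#'
#' @param mesh a [export_surface()] result.
#' @return Integer Euler characteristic.
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nrow(mesh$vertices) - ne + nrow(f)
}

#' Volume enclosed by a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; with outward
#' winding the result is positive and equals the enclosed volume in
#' cubic micrometers.
#'
#' @param mesh a [export_surface()] result.
#' @return Enclosed volume (um^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
            a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [export_surface()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh as VRML 2.0 (IndexedFaceSet)
#'
#' @param mesh a [export_surface()] result.
#' @param path output file (`.wrl`).
#' @return `path`, invisibly.
#' @export
write_vrml <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#VRML V2.0 utf8", "Shape {", " geometry IndexedFaceSet {",
               "  coord Coordinate {", "   point ["), con)
  writeLines(sprintf("    %.6g %.6g %.6g,", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(c("   ]", "  }", "  coordIndex ["), con)
  writeLines(sprintf("   %d, %d, %d, -1,", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  writeLines(c("  ]", " }", "}"), con)
  invisible(path)
}

#' Write a camera path as CSV
#'
#' Columns `index, x_um, y_um, z_um, fx, fy, fz, ux, uy, uz`, consumable
#' by any renderer.
#'
#' @param poses a [camera_poses()] result.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_path_csv <- function(poses, path) {
  df <- data.frame(index = seq_len(nrow(poses)) - 1L,
                   x_um = poses$x, y_um = poses$y, z_um = poses$z,
                   fx = poses$fx, fy = poses$fy, fz = poses$fz,
                   ux = poses$ux, uy = poses$uy, uz = poses$uz)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
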