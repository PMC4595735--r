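#' Generate a synthetic branching vessel tree
#'
#' Recursive bifurcating tube model used as ground truth for imaging
#' phantoms.  Starting from a root segment, every tip spawns two children
#' per level; child radius is `parent * radius_decay` and the child
#' direction deviates from the parent direction by `branch_angle` degrees
#' (plus seeded jitter) at opposite azimuths, so the tree spreads in 3D.
#' Child length shrinks by `length_decay` per level.
#'
#' Real arterial trees branch without touching themselves, and the
#' downstream network analysis assumes an embedded (non-anastomosing)
#' tube system, so placement is collision-aware: if the nominal direction
#' would bring the new segment closer than `clearance_um` to any
#' non-adjacent existing segment (surface to surface) or outside the
#' bounding box, a fixed fan of alternative azimuths and polar angles is
#' scored and the best-clearing candidate is used.  The candidate fan is
#' deterministic, so identical seeds still give bit-identical trees.  A
#' child whose endpoint would still leave the box has the offending
#' direction component mirrored.
#'
#' The default radius decay of 0.79 is the cube root of 1/2, i.e. the
#' symmetric-bifurcation value of Murray's law, a standard physiological
#' branching exponent.
#'
#' @param seed integer seed; identical seed and parameters give a
#'   bit-identical tree.
#' @param n_levels number of bifurcation levels (>= 0; 0 gives a single
#'   unbranched segment).
#' @param root_radius radius of the root segment (micrometers).
#' @param radius_decay per-level radius ratio in (0, 1].
#' @param branch_angle mean deviation of a child from its parent direction
#'   (degrees).
#' @param bounds 2 x 3 matrix `rbind(lo, hi)` of the allowed region in
#'   micrometers, columns (x, y, z).
#' @param trunk_length length of the root segment (micrometers); default
#'   is 28% of the smallest bounds span.
#' @param length_decay per-level segment length ratio.
#' @param jitter_deg half-width of the uniform jitter applied to the
#'   branch angle and azimuth (degrees).
#' @param clearance_um minimum surface-to-surface clearance kept between
#'   non-adjacent segments (micrometers).
#' @return An object of class `vessel_tree`: `nodes` (data.frame
#'   `id, x, y, z, radius`), `edges` (data.frame `parent, child`),
#'   `root_id`.
#' @export
generate_tree <- function(seed, n_levels = 4, root_radius = 26,
                          radius_decay = 0.79, branch_angle = 45,
                          bounds = rbind(c(0, 0, 0), c(760, 760, 760)),
                          trunk_length = NULL, length_decay = 0.78,
                          jitter_deg = 5, clearance_um = 12) {
  if (n_levels < 0) stop("`n_levels` must be >= 0")
  if (radius_decay <= 0 || radius_decay > 1)
    stop("`radius_decay` must lie in (0, 1]")
  if (root_radius <= 0) stop("`root_radius` must be positive")
  bounds <- as.matrix(bounds)
  if (!all(dim(bounds) == c(2, 3)) || any(bounds[2, ] <= bounds[1, ]))
    stop("`bounds` must be rbind(lo, hi) with hi > lo")
  span <- bounds[2, ] - bounds[1, ]
  if (is.null(trunk_length)) trunk_length <- 0.28 * min(span)

  root_pos <- bounds[1, ] + c(0.5, 0.5, 0) * span +
    c(0, 0, max(root_radius * 1.5, 0.05 * span[3]))
  dir0 <- c(0, 0, 1)
  tip0 <- root_pos + trunk_length * dir0
  safe_lo <- bounds[1, ] + root_radius
  safe_hi <- bounds[2, ] - root_radius
  if (any(root_pos < safe_lo - 1e-9) || any(tip0 > safe_hi + 1e-9) ||
      any(tip0 < safe_lo - 1e-9))
    stop("bounds too small to contain the root segment")

  with_seed(seed, {
    nodes <- list(c(root_pos, root_radius), c(tip0, root_radius))
    edges <- list()
    add_edge <- function(p, c) edges[[length(edges) + 1L]] <<- c(p, c)
    add_edge(1L, 2L)

    # orthonormal frame around a direction
    frame_of <- function(d) {
      a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- a - sum(a * d) * d
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(d[2] * e1[3] - d[3] * e1[2],
              d[3] * e1[1] - d[1] * e1[3],
              d[1] * e1[2] - d[2] * e1[1])
      cbind(e1, e2)
    }

    # surface-to-surface clearance of a candidate segment (base -> end,
    # radius r) against existing edges and the box walls.  The parent edge
    # (ending at the start node) is anatomical continuity and skipped; a
    # sibling edge (leaving the same start node) legitimately shares the
    # origin, so only the distal halves of both tubes are compared.
    seg_clearance <- function(base, end, r, skip_node) {
      ts <- seq(0, 1, by = 0.1)
      pts <- outer(rep(1, length(ts)), base) + outer(ts, end - base)
      cl <- Inf
      for (ei in seq_along(edges)) {
        e <- edges[[ei]]
        parent <- e[2] == skip_node
        sibling <- e[1] == skip_node
        a <- nodes[[e[1]]][1:3]; b <- nodes[[e[2]]][1:3]
        re <- max(nodes[[e[1]]][4], nodes[[e[2]]][4])
        if (sibling) a <- a + 0.5 * (b - a)         # distal half only
        if (parent) b <- a + 0.5 * (b - a)          # proximal half only
        p <- if (sibling || parent)
          pts[ts >= 0.5, , drop = FALSE] else pts
        ab <- b - a
        tt <- pmin(1, pmax(0, ((p[, 1] - a[1]) * ab[1] +
                                 (p[, 2] - a[2]) * ab[2] +
                                 (p[, 3] - a[3]) * ab[3]) /
                             max(sum(ab^2), 1e-12)))
        dd <- sqrt((p[, 1] - (a[1] + tt * ab[1]))^2 +
                     (p[, 2] - (a[2] + tt * ab[2]))^2 +
                     (p[, 3] - (a[3] + tt * ab[3]))^2)
        cl <- min(cl, min(dd) - r - re)
      }
      wall <- min(c(end - bounds[1, ], bounds[2, ] - end)) - r
      min(cl, wall)
    }

    tips <- list(list(id = 2L, dir = dir0, radius = root_radius,
                      len = trunk_length))
    lvl <- 0
    while (lvl < n_levels) {
      lvl <- lvl + 1
      new_tips <- list()
      for (tp in tips) {
        fr <- frame_of(tp$dir)
        phi0 <- runif(1, 0, 2 * pi)
        for (k in 0:1) {
          th_nom <- branch_angle + runif(1, -jitter_deg, jitter_deg)
          ph_nom <- phi0 + k * pi + runif(1, -jitter_deg, jitter_deg) *
            pi / 180
          len_full <- tp$len * length_decay
          r <- tp$radius * radius_decay
          base <- nodes[[tp$id]][1:3]
          # deterministic candidate fan: nominal first, then azimuth and
          # polar alternatives ordered by increasing deviation
          cand <- rbind(
            c(th_nom, 0),
            as.matrix(expand.grid(th = th_nom + c(0, 12, -12, 24),
                                  dph = c(30, -30, 60, -60, 90, -90,
                                          120, -120, 150)))
          )
          # mirror direction components that would exit the box, then clamp
          finalize <- function(d, len) {
            end <- base + len * d
            for (ax in 1:3) {
              if (end[ax] > bounds[2, ax] - r) d[ax] <- -abs(d[ax])
              if (end[ax] < bounds[1, ax] + r) d[ax] <- abs(d[ax])
            }
            d <- d / sqrt(sum(d^2))
            end <- base + len * d
            end <- pmin(pmax(end, bounds[1, ] + r), bounds[2, ] - r)
            list(d = d, end = end)
          }
          best <- NULL; best_cl <- -Inf; len <- len_full
          # crowded regions fall back to progressively shorter branches
          for (shrink in c(1, 0.75, 0.55)) {
            for (ci in seq_len(nrow(cand))) {
              th <- cand[ci, 1] * pi / 180
              ph <- ph_nom + cand[ci, 2] * pi / 180
              d <- cos(th) * tp$dir +
                sin(th) * (cos(ph) * fr[, 1] + sin(ph) * fr[, 2])
              fin <- finalize(d / sqrt(sum(d^2)), len_full * shrink)
              cl <- seg_clearance(base, fin$end, r, tp$id)
              # wall clamping may truncate the branch; a branch shorter
              # than its own junction blob is unusable, so penalize
              got <- sqrt(sum((fin$end - base)^2))
              if (got < max(3 * r, 0.3 * len_full)) cl <- cl - 1e4
              if (cl > best_cl) { best_cl <- cl; best <- fin
                len <- len_full * shrink }
              if (cl >= clearance_um) break
            }
            if (best_cl >= clearance_um) break
          }
          d <- best$d
          end <- best$end
          nodes[[length(nodes) + 1L]] <- c(end, r)
          cid <- length(nodes)
          add_edge(tp$id, cid)
          new_tips[[length(new_tips) + 1L]] <-
            list(id = cid, dir = d, radius = r, len = len)
        }
      }
      tips <- new_tips
    }

    nm <- do.call(rbind, nodes)
    em <- do.call(rbind, edges)
    structure(list(
      nodes = data.frame(id = seq_len(nrow(nm)), x = nm[, 1], y = nm[, 2],
                         z = nm[, 3], radius = nm[, 4]),
      edges = data.frame(parent = em[, 1], child = em[, 2]),
      root_id = 1L
    ), class = "vessel_tree")
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d nodes, %d edges, radii %.3g-%.3g um\n",
              nrow(x$nodes), nrow(x$edges),
              min(x$nodes$radius), max(x$nodes$radius)))
  invisible(x)
}

#' Ground-truth per-segment table of a vessel tree
#'
#' One row per tree edge with its length, mean diameter (radii are
#' linearly tapered along an edge, so the mean diameter is the mean of the
#' endpoint diameters) and frustum volume.  A segment here follows the
#' morphometric convention: a section of vasculature between two
#' bifurcations, between a bifurcation and an end point, or an isolated
#' section between two end points -- for a bifurcating tree that is
#' exactly one table row per edge.
#'
#' @param tree a [generate_tree()] result.
#' @return data.frame with columns `parent, child, length_um,
#'   mean_diameter_um, volume_um3`.
#' @export
tree_segment_table <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  n <- tree$nodes
  e <- tree$edges
  p <- as.matrix(n[e$parent, c("x", "y", "z")])
  q <- as.matrix(n[e$child, c("x", "y", "z")])
  len <- sqrt(rowSums((p - q)^2))
  r1 <- n$radius[e$parent]
  r2 <- n$radius[e$child]
  data.frame(
    parent = e$parent, child = e$child, length_um = len,
    mean_diameter_um = r1 + r2,
    volume_um3 = pi * len * (r1^2 + r1 * r2 + r2^2) / 3
  )
}

#' Count the branch points of a vessel tree
#'
#' A branch point is a node from which two (or more) child edges leave.
#' End points are not branch points.
#'
#' @param tree a [generate_tree()] result.
#' @return Integer count.
#' @export
tree_branch_count <- function(tree) {
  sum(table(tree$edges$parent) >= 2)
}

#' Rasterize a vessel tree into a binary voxel mask
#'
#' A voxel belongs to the vessel iff its center lies within the tube
#' radius of some edge's centerline, with the radius linearly interpolated
#' along the edge (tapered tube).  Parts of the tree extending beyond the
#' grid are clipped with a warning.
#'
#' @param tree a [generate_tree()] result (positions in micrometers).
#' @param shape grid shape `c(nz, ny, nx)`.
#' @param voxel_size voxel edge (micrometers).
#' @return A [voxel_volume()] with `mask` payload.
#' @export
voxelize_tree <- function(tree, shape, voxel_size) {
  stopifnot(inherits(tree, "vessel_tree"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1)) stop("`shape` must be c(nz, ny, nx)")
  if (nrow(tree$edges) == 0L)
    return(voxel_volume(array(0L, shape), voxel_size, "mask"))
  pos <- as.matrix(tree$nodes[, c("x", "y", "z")]) / voxel_size
  rad <- tree$nodes$radius / voxel_size
  if (any(!is.finite(pos))) stop("tree positions must be finite")
  res <- cpp_voxelize(pos, rad, as.matrix(tree$edges) - 1L, shape)
  if (res$clipped)
    warning("vessel tree extends beyond the voxel grid; clipped")
  voxel_volume(res$mask, voxel_size, "mask")
}

#' Parenchyma (sample hull) mask
#'
#' The tissue block surrounding the vessels: either an ellipsoid inscribed
#' in the grid (leaving `margin` voxels of exterior air, so the sample has
#' a genuine outside) or a margin-inset box.
#'
#' @param shape grid shape `c(nz, ny, nx)`.
#' @param voxel_size voxel edge (micrometers).
#' @param kind `"ellipsoid"` or `"box"`.
#' @param margin exterior air margin in voxels.
#' @return A [voxel_volume()] with `mask` payload.
#' @export
make_parenchyma <- function(shape, voxel_size, kind = c("ellipsoid", "box"),
                            margin = 4) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  ctr <- (shape - 1) / 2
  if (kind == "box") {
    m <- array(0L, shape)
    m[(1 + margin):(shape[1] - margin), (1 + margin):(shape[2] - margin),
      (1 + margin):(shape[3] - margin)] <- 1L
  } else {
    ax <- ctr - margin
    z <- ((seq_len(shape[1]) - 1) - ctr[1]) / ax[1]
    y <- ((seq_len(shape[2]) - 1) - ctr[2]) / ax[2]
    x <- ((seq_len(shape[3]) - 1) - ctr[3]) / ax[3]
    m <- array(0L, shape)
    zz <- array(z^2, shape)
    yy <- aperm(array(y^2, shape[c(2, 1, 3)]), c(2, 1, 3))
    xx <- aperm(array(x^2, shape[c(3, 2, 1)]), c(3, 2, 1))
    m[zz + yy + xx <= 1] <- 1L
  }
  voxel_volume(m, voxel_size, "mask")
}

#' Build delta/beta material grids from masks
#'
#' Produces the complex-refractive-index decomposition of the phantom:
#' the real decrement `delta` (drives phase shift) and absorption index
#' `beta` (drives attenuation) of tissue on parenchyma-minus-vessel
#' voxels, and exactly 0 -- the surrounding-air value -- on vessel lumina
#' and outside the sample.  Vessel voxels carrying the exterior-air optical
#' constants is the contrast mechanism of the whole approach: dehydrated
#' tissue around air-filled lumina.
#'
#' The shipped default fixes `delta = 400 * beta`, matching the
#' delta-over-beta ratio used by the phase-retrieval stage; only `beta` is
#' a free material parameter.
#'
#' @param vessel_mask binary [voxel_volume()] of vessel lumina.
#' @param parenchyma_mask binary [voxel_volume()] of the tissue hull;
#'   must contain every vessel voxel.
#' @param beta_tissue absorption index of the tissue (dimensionless).
#' @param delta_tissue refractive-index decrement of the tissue; default
#'   `400 * beta_tissue`.
#' @return An object of class `material_volume` with fields `delta`,
#'   `beta` (3D arrays) and `voxel_size`.
#' @export
to_material_volume <- function(vessel_mask, parenchyma_mask,
                               beta_tissue = 1e-9,
                               delta_tissue = 400 * beta_tissue) {
  v <- as_mask_array(vessel_mask)
  p <- as_mask_array(parenchyma_mask)
  if (!all(dim(v) == dim(p))) stop("masks must share shape")
  if (any(v > p))
    stop(sprintf("%d vessel voxels lie outside the parenchyma", sum(v > p)))
  if (beta_tissue < 0 || delta_tissue < 0)
    stop("delta and beta must be non-negative")
  tissue <- p & !v
  delta <- array(0, dim(v)); delta[tissue] <- delta_tissue
  beta <- array(0, dim(v)); beta[tissue] <- beta_tissue
  structure(list(delta = delta, beta = beta,
                 voxel_size = vol_voxel_size(vessel_mask)),
            class = "material_volume")
}

#' @export
print.material_volume <- function(x, ...) {
  d <- dim(x$delta)
  cat(sprintf(paste0("<material_volume> %d x %d x %d (z,y,x), %.4g um/voxel, ",
                     "delta/beta = %.4g\n"), d[1], d[2], d[3], x$voxel_size,
              max(x$delta) / max(max(x$beta), .Machine$double.xmin)))
  invisible(x)
}

#' Write / read a vessel tree as CSV
#'
#' `nodes.csv` holds `id, x, y, z, radius` (micrometers) and `edges.csv`
#' holds `parent, child`.
#'
#' @param tree a [generate_tree()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (writer); a `vessel_tree` (reader).
#' @export
write_tree_csv <- function(tree, dir) {
  stopifnot(inherits(tree, "vessel_tree"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tree$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  write.csv(tree$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_tree_csv
#' @export
read_tree_csv <- function(dir) {
  nodes <- read.csv(file.path(dir, "nodes.csv"))
  edges <- read.csv(file.path(dir, "edges.csv"))
  structure(list(nodes = nodes, edges = edges, root_id = 1L),
            class = "vessel_tree")
}

#' One-call vascular phantom
#'
#' Convenience constructor for the full synthetic study object: a seeded
#' vessel tree grown inside an ellipsoidal parenchyma, its voxelized
#' ground-truth mask (intersected with the parenchyma so the material
#' volume is consistent), and the delta/beta material grids.
#'
#' The default scale (128^3 voxels at 5.92 um, root radius 26 um over four
#' bifurcation levels) puts vessel diameters in the 3.5-9 voxel range
#' (about 23-52 um), so the per-segment diameter spectrum straddles the
#' 30 um reporting threshold of the network stage.
#'
#' @param seed integer seed.
#' @param shape grid shape `c(nz, ny, nx)`.
#' @param voxel_size voxel edge (micrometers).
#' @param n_levels bifurcation levels.
#' @param root_radius root vessel radius (micrometers).
#' @param ... further arguments passed to [generate_tree()].
#' @return list with `tree`, `vessel_mask`, `parenchyma_mask`, `material`,
#'   `truth` (the [tree_segment_table()]).
#' @export
vascular_phantom <- function(seed, shape = c(128, 128, 128),
                             voxel_size = 5.92, n_levels = 4,
                             root_radius = 26, ...) {
  shape <- as.integer(shape)
  ext <- shape[c(3, 2, 1)] * voxel_size  # bounds are (x, y, z)
  inset <- 0.12 * ext
  bounds <- rbind(inset, ext - inset)
  tree <- generate_tree(seed, n_levels = n_levels,
                        root_radius = root_radius, bounds = bounds, ...)
  vm <- voxelize_tree(tree, shape, voxel_size)
  pm <- make_parenchyma(shape, voxel_size, kind = "ellipsoid", margin = 4)
  vm$data <- array(as.integer(vm$data & pm$data), shape)
  list(tree = tree,
       vessel_mask = vm,
       parenchyma_mask = pm,
       material = to_material_volume(vm, pm),
       truth = tree_segment_table(tree))
}
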