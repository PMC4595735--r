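# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately implemented here from first principles (plain
# loops, exhaustive enumeration, explicit DFT matrices) so they do not
# share code with the package internals they check.

# axis-aligned cylinder mask along x, centre (cy, cz), radius r voxels
cylinder_mask <- function(nz, ny, nx, x0, x1, cy, cz, r, voxel_size = 1) {
  m <- array(0L, c(nz, ny, nx))
  for (x in x0:x1) for (y in seq_len(ny)) for (z in seq_len(nz))
    if ((y - cy)^2 + (z - cz)^2 <= r^2) m[z, y, x] <- 1L
  voxel_volume(m, voxel_size, "mask")
}

# brute-force traversal oracle on a vessel tree: counts branch points
# (nodes with >= 2 children) and segments (edges of a bifurcating tree)
# by explicit recursion from the root
tree_oracle <- function(tree) {
  children <- split(tree$edges$child, tree$edges$parent)
  n_branch <- 0L
  n_seg <- 0L
  walk <- function(id) {
    ch <- children[[as.character(id)]]
    if (is.null(ch)) return(invisible())
    if (length(ch) >= 2) n_branch <<- n_branch + 1L
    for (c in ch) {
      n_seg <<- n_seg + 1L
      walk(c)
    }
  }
  walk(tree$root_id)
  list(n_branch = n_branch, n_segments = n_seg)
}

# plain R BFS connected-component count (6- or 26-connectivity)
flood_fill_components <- function(mask_arr, connectivity = 26) {
  d <- dim(mask_arr)
  lab <- array(0L, d)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  ncomp <- 0L
  idx <- which(mask_arr == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    if (lab[p[1], p[2], p[3]] > 0L) next
    ncomp <- ncomp + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- ncomp
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nz <- q[1] + offs$dz[o]; ny <- q[2] + offs$dy[o]
        nx <- q[3] + offs$dx[o]
        if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] ||
            nx < 1 || nx > d[3]) next
        if (mask_arr[nz, ny, nx] == 1L && lab[nz, ny, nx] == 0L) {
          lab[nz, ny, nx] <- ncomp
          queue[[length(queue) + 1L]] <- c(nz, ny, nx)
        }
      }
    }
  }
  ncomp
}

# exhaustive shortest-path enumeration over a skeleton_graph's segment
# list: all simple node paths between two node ids, minimum total length
enumerate_shortest <- function(graph, from, to) {
  segs <- graph$segments
  segs <- segs[!is.na(segs$node_a) & !is.na(segs$node_b), , drop = FALSE]
  best <- Inf
  walk <- function(node, visited, acc) {
    if (acc >= best) return(invisible())
    if (node == to) { best <<- min(best, acc); return(invisible()) }
    inc <- which(segs$node_a == node | segs$node_b == node)
    for (i in inc) {
      nxt <- if (segs$node_a[i] == node) segs$node_b[i] else segs$node_a[i]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), acc + segs$length_um[i])
    }
  }
  walk(from, from, 0)
  best
}

# independent Euler characteristic of a triangle mesh
euler_oracle <- function(mesh) {
  f <- mesh$faces
  ekeys <- unique(c(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                    paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                    paste(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
  nrow(mesh$vertices) - length(ekeys) + nrow(f)
}

# analytic parallel-beam sinogram of a centred uniform disc
disc_sinogram <- function(n, n_angles, radius_um, pixel_um) {
  c0 <- (n - 1) / 2
  u <- ((0:(n - 1)) - c0) * pixel_um
  p <- ifelse(abs(u) < radius_um,
              2 * sqrt(pmax(radius_um^2 - u^2, 0)), 0)
  array(rep(p, each = n_angles), c(n_angles, 1, n))
}
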