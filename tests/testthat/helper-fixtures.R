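# Shared fixtures, built in code.

# Regular tetrahedron with edge length 1.
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(8)  # edge length 1
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  triangle_mesh(v, f)
}

# Single triangle with area `area` in the z = 0 plane.
single_triangle_mesh <- function(area = 6) {
  triangle_mesh(rbind(c(0, 0, 0), c(2 * area, 0, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3)))
}

# Planar n x n grid of unit squares split into triangles; interior
# vertices have vertex-wise area exactly 1 (six incident faces of area
# 1/2 each).
grid_mesh <- function(n = 20L) {
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  coords <- expand.grid(i = 0:n, j = 0:n)
  v <- cbind(coords$i, coords$j, 0)
  f <- matrix(0L, 2L * n * n, 3L)
  k <- 0L
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      cc <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      f[k + 1L, ] <- c(a, b, d)
      f[k + 2L, ] <- c(a, d, cc)
      k <- k + 2L
    }
  }
  triangle_mesh(v, f)
}

# Interior vertices of grid_mesh(n) (all six-face vertices, area 1).
grid_interior <- function(n = 20L) {
  coords <- expand.grid(i = 0:n, j = 0:n)
  which(coords$i > 0 & coords$i < n & coords$j > 0 & coords$j < n)
}

# Independent per-vertex area oracle: loop over faces, accumulate a
# third of each face area at each corner.
vertex_area_oracle <- function(mesh) {
  out <- numeric(n_vertices(mesh))
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[k, ]
    p <- mesh$vertices[tri, ]
    a <- 0.5 * sqrt(sum(pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
    out[tri] <- out[tri] + a / 3
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Independent adjacency oracle from the face list.
neighbor_oracle <- function(mesh, v) {
  f <- mesh$faces
  hit <- f[rowSums(f == v) > 0L, , drop = FALSE]
  sort(setdiff(unique(as.integer(hit)), v))
}

# Grow a connected vertex patch from `start` until its summed area
# first reaches `target_area`.
grow_patch <- function(mesh, areas, start, target_area) {
  nb <- mesh_adjacency(mesh)$neighbors
  patch <- start
  frontier <- start
  while (region_area(areas, patch) < target_area) {
    nxt <- setdiff(sort(unique(unlist(nb[frontier]))), patch)
    if (length(nxt) == 0L) break
    for (v in nxt) {
      patch <- c(patch, v)
      if (region_area(areas, patch) >= target_area) break
    }
    frontier <- nxt
  }
  sort(patch)
}
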