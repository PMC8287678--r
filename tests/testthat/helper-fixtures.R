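# in-code fixtures shared across test files

# unit square in the z = 0 plane, two triangles
unit_square_mesh <- function() {
  surface_mesh(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               triangles = rbind(c(1, 2, 3), c(1, 3, 4)))
}

# regular triangulated grid on [0, lx] x [0, ly] at z = 0
flat_grid_mesh <- function(nx = 10, ny = 10, lx = 1, ly = 1) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  v <- as.matrix(expand.grid(x = xs, y = ys))
  v <- cbind(v, 0)
  id <- function(i, j) (j - 1) * (nx + 1) + i
  tris <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    tris[[length(tris) + 1]] <- rbind(
      c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
      c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(v, do.call(rbind, tris))
}

grid_interior <- function(nx, ny) {
  id <- function(i, j) (j - 1) * (nx + 1) + i
  as.vector(outer(2:nx, 2:ny, id))
}

# independent shortest-path oracle (Bellman-Ford relaxation to fixpoint)
brute_force_geodesic <- function(mesh, from) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  nv <- nrow(mesh$vertices)
  d <- rep(Inf, nv)
  d[from] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(e))) {
      i <- e[k, 1]; j <- e[k, 2]
      if (d[i] + len[k] < d[j] - 1e-15) { d[j] <- d[i] + len[k]; changed <- TRUE }
      if (d[j] + len[k] < d[i] - 1e-15) { d[i] <- d[j] + len[k]; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# wall field whose vector at time t is scale(t) * dir at every vertex
uniform_field <- function(mesh, times, dir, scale) {
  nv <- nrow(mesh$vertices)
  vec <- array(0, c(nv, length(times), 3))
  for (k in 1:3) vec[, , k] <- outer(rep(dir[k], nv), scale)
  wall_field(mesh, times, vec)
}

# seeded cardiac-like waveform with randomized indices
random_waveform <- function(seed, n_cycles = 1) {
  set.seed(seed)
  make_doppler_waveform(vps = runif(1, 70, 130), ved = runif(1, 30, 60),
                        period = runif(1, 0.7, 1.1), n_cycles = n_cycles)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
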