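# Independent oracles used across the suite. These deliberately use
# different algorithms than the package internals they check.

# Generalized winding number inside test (Van Oosterom & Strackee solid
# angle): a point is inside a closed mesh iff the summed solid angle is
# ~ 4*pi. Independent of the nearest-feature signed-distance test used by
# the collision narrow phase.
winding_inside <- function(points, mesh_pos, mesh_faces) {
  vapply(seq_len(nrow(points)), function(pi_) {
    p <- points[pi_, ]
    a <- sweep(mesh_pos[mesh_faces[, 1], , drop = FALSE], 2, p, "-")
    b <- sweep(mesh_pos[mesh_faces[, 2], , drop = FALSE], 2, p, "-")
    c_ <- sweep(mesh_pos[mesh_faces[, 3], , drop = FALSE], 2, p, "-")
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c_^2))
    cx <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    num <- rowSums(a * cx)
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * c_) * lb +
      rowSums(b * c_) * la
    omega <- sum(2 * atan2(num, den))
    omega > 2 * pi   # ~4*pi inside, ~0 outside
  }, TRUE)
}

# All-pairs brute-force contact incidence: for every ordered cell pair,
# every vertex of A inside B (winding test). Returns a character key set.
brute_force_contact_set <- function(scene) {
  n <- length(scene$cells)
  keys <- character(0)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    inside <- winding_inside(scene$cells[[a]]$positions,
                             scene$cells[[b]]$positions,
                             scene$cells[[b]]$faces)
    if (any(inside))
      keys <- c(keys, sprintf("%d:%d:%d", a, which(inside), b))
  }
  sort(keys)
}

fast_contact_set <- function(scene) {
  ct <- find_contacts(scene)
  sort(sprintf("%d:%d:%d", ct$cell, ct$vertex, ct$violated_cell))
}

# random non-overlapping-ish scene of small icosphere cells
random_cell_scene <- function(n_cells = 8, subdivisions = 1, spread = 3.2,
                              params = default_params()) {
  cells <- lapply(seq_len(n_cells), function(i) {
    icosphere(subdivisions, radius = 1,
              center = stats::runif(3, -spread / 2, spread / 2), id = i)
  })
  mc_scene(cells, params = params)
}

# unit cube triangulated into 12 outward-wound faces, as a plain mesh list
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  faces <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  list(positions = v, faces = faces)
}
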