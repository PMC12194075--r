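#' Build the closed triangulated cortex mesh of a single cell
#'
#' Generates an icosphere: a regular icosahedron subdivided `subdivisions`
#' times by edge-midpoint insertion, with every vertex projected back onto
#' the sphere. Shared midpoints are merged by exact index-pair keys, so the
#' mesh is watertight by construction and bit-identical across calls with
#' the same arguments. Subdivision level 3 gives the 642-vertex / 1280-face
#' cortex used for production cells; level 2 (162 / 320) is the fast default
#' for desk-scale runs.
#'
#' The returned cell carries, besides the triangulation, the per-edge rest
#' lengths (`l_rest`, `l0`, both initialised to the built edge lengths), a
#' per-edge stiffness `k`, the rest volume `V0` (the mesh's signed volume),
#' and a per-vertex region band coordinate: the polar angle from the apical
#' pole expressed as a percentage (0 = apical pole, 50 = equator, 100 =
#' basal pole). Regions such as "apical 0--50%" are selected against this
#' coordinate; membership is assigned here, on the undeformed sphere, and
#' travels with the vertices as the cell deforms.
#'
#' @param subdivisions Non-negative integer subdivision level.
#' @param radius Sphere radius (model length units), must be positive.
#' @param center Numeric length-3 center of the cell.
#' @param apical_axis Numeric length-3 direction of the apical pole
#'   (normalised internally; must be non-zero).
#' @param k Cortical stiffness assigned to every edge.
#' @param type Cell type label (e.g. `"endoderm"`, `"ectoderm"`).
#' @param id Integer cell id.
#' @return An object of class `mc_cell`.
#' @examples
#' cell <- icosphere(2)
#' nrow(cell$positions)  # 162
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0),
                      apical_axis = c(0, 0, 1), k = 0.5, type = "cell",
                      id = 1L) {
  if (!is.numeric(subdivisions) || length(subdivisions) != 1 ||
      subdivisions < 0 || subdivisions != round(subdivisions))
    stop("'subdivisions' must be a single non-negative integer")
  if (!is.finite(radius) || radius <= 0)
    stop("'radius' must be a finite positive number")
  if (length(center) != 3 || any(!is.finite(center)))
    stop("'center' must be a finite length-3 vector")
  if (length(apical_axis) != 3 || any(!is.finite(apical_axis)))
    stop("'apical_axis' must be a finite length-3 vector")
  nax <- sqrt(sum(apical_axis^2))
  if (nax == 0) stop("'apical_axis' must have non-zero length")
  apical_axis <- apical_axis / nax

  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))

  lvl <- as.integer(subdivisions)
  while (lvl > 0) {
    sub <- .subdivide_faces(V, F)
    V <- sub$V / sqrt(rowSums(sub$V^2))   # project midpoints to the sphere
    F <- sub$F
    lvl <- lvl - 1L
  }
  F <- .orient_outward(V, F)
  storage.mode(F) <- "integer"
  dimnames(F) <- NULL

  pos <- V * radius
  pos <- sweep(pos, 2, center, "+")
  edges <- edges_from_faces(F)
  lens <- sqrt(rowSums((pos[edges[, 1], , drop = FALSE] -
                        pos[edges[, 2], , drop = FALSE])^2))

  cell <- structure(list(
    positions = pos,
    edges = edges,
    faces = F,
    l_rest = lens,
    l0 = lens,
    k = rep_len(k, nrow(edges)),
    band = band_coordinate(pos, center, apical_axis),
    center = as.numeric(center),
    apical_axis = apical_axis,
    radius = radius,
    V0 = NA_real_,
    type = type,
    adhesive = rep(FALSE, nrow(pos)),
    id = as.integer(id)
  ), class = "mc_cell")
  cell$V0 <- signed_volume(cell)
  cell
}

# One midpoint-insertion subdivision round; winding of the parent face is
# inherited by all four children. Midpoints are merged by exact (min, max)
# vertex-index keys.
.subdivide_faces <- function(V, F) {
  nf <- nrow(F)
  e_all <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- pmin(e_all[, 1], e_all[, 2]) * (nrow(V) + 1) +
    pmax(e_all[, 1], e_all[, 2])
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  mid <- (V[e_all[first, 1], , drop = FALSE] +
          V[e_all[first, 2], , drop = FALSE]) / 2
  mid_id <- nrow(V) + seq_along(uk)
  m12 <- mid_id[idx[seq_len(nf)]]
  m23 <- mid_id[idx[nf + seq_len(nf)]]
  m31 <- mid_id[idx[2L * nf + seq_len(nf)]]
  list(V = rbind(V, mid),
       F = rbind(cbind(F[, 1], m12, m31),
                 cbind(F[, 2], m23, m12),
                 cbind(F[, 3], m31, m23),
                 cbind(m12, m23, m31)))
}

# Flip faces whose normal points toward the centroid (valid for the convex
# sphere meshes built here), giving consistent outward winding.
.orient_outward <- function(V, F) {
  ctr <- colMeans(V)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  n <- .rowcross(b - a, c_ - a)
  fc <- (a + b + c_) / 3
  flip <- rowSums(n * sweep(fc, 2, ctr, "-")) < 0
  F[flip, ] <- F[flip, c(1, 3, 2)]
  F
}

.rowcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Derive the unique undirected edge list from a face matrix
#'
#' @param faces Integer matrix with one vertex-index triple per row.
#' @return Two-column integer matrix, each row an unordered vertex pair,
#'   sorted by (first, second) index.
#' @export
edges_from_faces <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}

#' Signed volume of a closed triangulated mesh
#'
#' Divergence-theorem volume: one third of the sum over faces of the dot
#' product between any face point and the (area-scaled) outward face normal.
#' Positive for consistently outward-wound closed meshes and independent of
#' the coordinate origin. The mesh is checked for closure (every edge
#' bordering exactly two faces) before evaluation.
#'
#' @param mesh An `mc_cell`, or any list with `positions` and `faces`.
#' @return Signed volume (model length units cubed).
#' @export
signed_volume <- function(mesh) {
  pos <- mesh$positions
  F <- mesh$faces
  .check_closed(F)
  a <- pos[F[, 1], , drop = FALSE]
  b <- pos[F[, 2], , drop = FALSE]
  c_ <- pos[F[, 3], , drop = FALSE]
  sum(rowSums(a * .rowcross(b - a, c_ - a))) / 6
}

#' Total surface area of a triangulated mesh
#' @inheritParams signed_volume
#' @return Sum of triangle areas.
#' @export
surface_area <- function(mesh) {
  pos <- mesh$positions
  F <- mesh$faces
  a <- pos[F[, 1], , drop = FALSE]
  n <- .rowcross(pos[F[, 2], , drop = FALSE] - a,
                 pos[F[, 3], , drop = FALSE] - a)
  sum(sqrt(rowSums(n^2))) / 2
}

.check_closed <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2))
    stop("mesh is not closed: some edges do not border exactly 2 faces")
  invisible(TRUE)
}

#' Region band coordinate of cortex vertices
#'
#' Position on the apico-basal arc expressed as a percentage of the polar
#' angle: `100 * theta / pi`, where `theta` is the angle between
#' (vertex - center) and the apical axis. 0 at the apical pole, 50 on the
#' equator, 100 at the basal pole. All region selections ("apical 0--50%",
#' "adhesive 20--65%", ...) are defined against this coordinate.
#'
#' @param positions Numeric matrix (n x 3) or length-3 vector.
#' @param center Cell center the polar angle is measured from.
#' @param apical_axis Direction of the apical pole (non-zero).
#' @return Numeric vector of band coordinates in \[0, 100\].
#' @export
band_coordinate <- function(positions, center, apical_axis) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  nax <- sqrt(sum(apical_axis^2))
  if (!is.finite(nax) || nax == 0)
    stop("'apical_axis' must have non-zero length")
  u <- apical_axis / nax
  d <- sweep(positions, 2, center, "-")
  dn <- sqrt(rowSums(d^2))
  if (any(dn == 0)) stop("vertex coincides with the cell center")
  ct <- pmin(1, pmax(-1, (d %*% u)[, 1] / dn))
  100 * acos(ct) / pi
}

#' Select the vertices and edges of a region band
#'
#' Vertices whose band coordinate lies in `[band[1], band[2]]` (inclusive),
#' and the edges whose two endpoints are both selected. Requiring both
#' endpoints keeps edge membership deterministic and avoids half-constricted
#' edges on the band boundary.
#'
#' @param cell An `mc_cell`.
#' @param band Numeric length-2, band start and end in percent,
#'   `0 <= band[1] <= band[2] <= 100`.
#' @return List with integer `vertices` and `edges` (row indices into the
#'   cell's edge matrix).
#' @export
select_region <- function(cell, band) {
  if (length(band) != 2 || band[1] > band[2] || band[1] < 0 || band[2] > 100)
    stop("'band' must be c(start, end) with 0 <= start <= end <= 100")
  vs <- which(cell$band >= band[1] & cell$band <= band[2])
  inset <- logical(nrow(cell$positions))
  inset[vs] <- TRUE
  es <- which(inset[cell$edges[, 1]] & inset[cell$edges[, 2]])
  list(vertices = vs, edges = es)
}

#' Outward unit vertex normals of a closed mesh
#'
#' Per-vertex average of the adjacent unit face normals, normalised. The
#' default weights each face by its incident corner angle, which is robust
#' to how quadrilateral patches happen to be triangulated (a cube corner
#' gets the symmetric `(+-1, +-1, +-1)/sqrt(3)` regardless of where the
#' face diagonals run) and skips degenerate zero-area faces naturally.
#' `weighting = "area"` uses the raw cross-product (area-vector) sum
#' instead -- the accumulation the volume force is built on.
#'
#' @inheritParams signed_volume
#' @param weighting `"angle"` (default) or `"area"`.
#' @return Numeric matrix (n x 3) of unit normals.
#' @export
vertex_normals <- function(mesh, weighting = c("angle", "area")) {
  weighting <- match.arg(weighting)
  pos <- mesh$positions
  F <- mesh$faces
  a <- pos[F[, 1], , drop = FALSE]
  b <- pos[F[, 2], , drop = FALSE]
  c_ <- pos[F[, 3], , drop = FALSE]
  n <- .rowcross(b - a, c_ - a)
  out <- matrix(0, nrow(pos), 3)
  if (weighting == "area") {
    for (j in 1:3)
      for (d in 1:3)
        out[, d] <- out[, d] + tapply_add(F[, j], n[, d], nrow(pos))
  } else {
    area2 <- sqrt(rowSums(n^2))
    ok <- area2 > 1e-300            # degenerate faces contribute nothing
    nunit <- n[ok, , drop = FALSE] / area2[ok]
    Fk <- F[ok, , drop = FALSE]
    corner_angle <- function(p, q, r) {
      u1 <- q - p; u2 <- r - p
      cosang <- rowSums(u1 * u2) /
        (sqrt(rowSums(u1^2)) * sqrt(rowSums(u2^2)))
      acos(pmin(1, pmax(-1, cosang)))
    }
    ak <- a[ok, , drop = FALSE]
    bk <- b[ok, , drop = FALSE]
    ck <- c_[ok, , drop = FALSE]
    w <- cbind(corner_angle(ak, bk, ck),
               corner_angle(bk, ck, ak),
               corner_angle(ck, ak, bk))
    for (j in 1:3)
      for (d in 1:3)
        out[, d] <- out[, d] + tapply_add(Fk[, j], w[, j] * nunit[, d],
                                          nrow(pos))
  }
  nn <- sqrt(rowSums(out^2))
  nn[nn < 1e-300] <- 1
  out / nn
}

tapply_add <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Validate a cell mesh
#'
#' Checks the structural invariants every simulated cell must satisfy:
#' closed 2-manifold (each edge borders exactly two faces), Euler
#' characteristic V - E + F = 2, consistent outward winding (positive signed
#' volume), positive edge rest lengths and non-negative stiffness.
#'
#' @param cell An `mc_cell`.
#' @return Invisibly `TRUE`; errors with a diagnostic otherwise.
#' @export
validate_mesh <- function(cell) {
  V <- nrow(cell$positions)
  E <- nrow(cell$edges)
  F <- nrow(cell$faces)
  .check_closed(cell$faces)
  if (V - E + F != 2)
    stop(sprintf("Euler characteristic is %d, expected 2", V - E + F))
  vol <- signed_volume(cell)
  if (!(vol > 0))
    stop("signed volume is not positive; winding is not outward")
  if (!is.null(cell$l0) && any(cell$l0 <= 0))
    stop("all edge rest lengths must be positive")
  if (!is.null(cell$k) && any(cell$k < 0))
    stop("edge stiffness must be non-negative")
  if (!is.null(cell$band) && (any(cell$band < 0) || any(cell$band > 100)))
    stop("band coordinates must lie in [0, 100]")
  invisible(TRUE)
}

#' @export
print.mc_cell <- function(x, ...) {
  cat(sprintf("<mc_cell %d '%s'> %d vertices, %d edges, %d faces\n",
              x$id, x$type, nrow(x$positions), nrow(x$edges), nrow(x$faces)))
  cat(sprintf("  V = %.4f (V0 = %.4f), center = (%.2f, %.2f, %.2f)\n",
              signed_volume(x), x$V0, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}
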