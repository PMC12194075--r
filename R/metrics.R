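#' Apico-basal and lateral extents of a cell
#'
#' Height is the extent of the vertex positions projected on the cell's
#' apical axis; width is the diameter (maximum pairwise distance) of the
#' positions projected onto the plane perpendicular to it.
#'
#' @param cell An `mc_cell`.
#' @return List with `height` and `width`.
#' @export
cell_extents <- function(cell) {
  u <- cell$apical_axis
  h <- cell$positions %*% u
  lat <- cell$positions - h %*% t(u)
  # diameter of the projected set: max pairwise distance in the plane
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  xy <- cbind(lat %*% e1, lat %*% e2)
  hull <- grDevices::chull(xy)
  d <- stats::dist(xy[hull, , drop = FALSE])
  list(height = diff(range(h)), width = max(d))
}

#' Cell elongation ratio
#'
#' Apico-basal extent divided by the maximum lateral extent perpendicular
#' to the apical axis; 1 for an undeformed sphere, above 1 for columnar
#' cells, below 1 for flattened ones.
#'
#' @param cell An `mc_cell`.
#' @return Elongation ratio.
#' @export
cell_elongation <- function(cell) {
  ext <- cell_extents(cell)
  ext$height / ext$width
}

#' Sphericity of a cell
#'
#' `pi^(1/3) * (6 V)^(2/3) / A`; equals 1 for a perfect sphere and
#' decreases with any shape deviation.
#'
#' @param cell An `mc_cell`.
#' @return Sphericity in (0, 1].
#' @export
sphericity <- function(cell) {
  V <- signed_volume(cell)
  A <- surface_area(cell)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Vertical and horizontal extents of the apical area
#'
#' Extents of the apical-band vertex set projected on two tangent
#' directions of the plate frame at the cell: `vertical` along the given
#' in-plate meridian direction, `horizontal` perpendicular to it (both
#' orthogonalised against the cell's apical axis).
#'
#' @param cell An `mc_cell`.
#' @param vertical Length-3 direction defining "vertical" in the plate
#'   frame (projected onto the plane perpendicular to the apical axis).
#' @param band Apical band (percent) whose vertices are measured.
#' @return Named numeric vector `c(vertical =, horizontal =)`.
#' @export
apical_extents <- function(cell, vertical, band = c(0, 20)) {
  sel <- select_region(cell, band)
  if (!length(sel$vertices)) stop("apical band selects no vertex")
  u <- cell$apical_axis
  v <- vertical - sum(vertical * u) * u
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("'vertical' is parallel to the apical axis")
  v <- v / nv
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  p <- cell$positions[sel$vertices, , drop = FALSE]
  c(vertical = diff(range(p %*% v)), horizontal = diff(range(p %*% w)))
}

#' Inward displacement of the plate center
#'
#' Signed displacement of the plate-center cell's centroid along the inward
#' oral axis, relative to a reference scene (usually the initial state) and
#' measured in the scene frame (centroid-relative), so rigid translations
#' of the whole scene do not register. Positive values mean the plate has
#' moved inward.
#'
#' @param scene Current `mc_scene`.
#' @param ref Reference `mc_scene` (same cells; e.g. the scene at t = 0).
#' @param cell Id of the plate-center cell.
#' @param oral_axis Outward oral axis (defaults to the scene's
#'   `"oral_axis"` attribute, else +z).
#' @return Invagination depth (model length units).
#' @export
invagination_depth <- function(scene, ref, cell,
                               oral_axis = attr(scene, "oral_axis")) {
  if (is.null(oral_axis)) oral_axis <- c(0, 0, 1)
  u <- oral_axis / sqrt(sum(oral_axis^2))
  now <- scene_centers(scene)
  then <- scene_centers(ref)
  rel_now <- now[cell, ] - colMeans(now)
  rel_then <- then[cell, ] - colMeans(then)
  sum((rel_then - rel_now) * u)
}

#' Blastoporal opening diameter
#'
#' Diameter of the blastoporal rim, found by an azimuthal surface walk: the
#' vertices of the outer (ectodermal) layer are binned into azimuthal
#' sectors around the oral axis, and each sector's rim candidate is its
#' vertex furthest along the axis. If the surface at the axis is level with
#' or above the rim (no fold: the plate has not moved inward past the
#' rim) the scene has no opening and 0 is reported; otherwise the opening
#' diameter is twice the mean axis distance of the rim candidates.
#'
#' @param scene An `mc_scene`.
#' @param oral_axis Outward oral axis (defaults to the scene's attribute,
#'   else +z).
#' @param n_sectors Number of azimuthal sectors for the rim walk.
#' @return Opening diameter (0 when no invagination fold exists).
#' @export
opening_diameter <- function(scene, oral_axis = attr(scene, "oral_axis"),
                             n_sectors = 24) {
  if (is.null(oral_axis)) oral_axis <- c(0, 0, 1)
  u <- oral_axis / sqrt(sum(oral_axis^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])

  types <- vapply(scene$cells, function(c) c$type, "")
  outer_cells <- if (any(types == "ectoderm")) which(types == "ectoderm")
    else seq_along(scene$cells)
  all_pos <- do.call(rbind, lapply(scene$cells, function(c) c$positions))
  out_pos <- do.call(rbind,
                     lapply(scene$cells[outer_cells],
                            function(c) c$positions))
  O <- colMeans(scene_centers(scene))

  rel_all <- sweep(all_pos, 2, O, "-")
  h_all <- rel_all %*% u
  rho_all <- sqrt(rowSums(rel_all^2) - h_all^2)

  rel_out <- sweep(out_pos, 2, O, "-")
  h_out <- rel_out %*% u
  rho_out <- sqrt(pmax(0, rowSums(rel_out^2) - h_out^2))
  phi <- atan2(rel_out %*% e2, rel_out %*% e1)
  sector <- pmin(n_sectors, 1 + floor((phi + pi) / (2 * pi) * n_sectors))

  rim_idx <- vapply(split(seq_len(nrow(out_pos)), sector),
                    function(ix) ix[which.max(h_out[ix])], 1L)
  rim_h <- mean(h_out[rim_idx])
  rim_rho <- mean(rho_out[rim_idx])

  # fold test: the surface column at the axis must lie below the rim
  near_axis <- rho_all < 0.25 * max(rho_all)
  if (!any(near_axis)) return(0)
  center_h <- max(h_all[near_axis])
  tol <- 0.05 * diff(range(h_all))
  if (center_h >= rim_h - tol) return(0)
  2 * rim_rho
}

#' Per-cell shape measurements of a scene
#'
#' @param scene An `mc_scene`.
#' @return Data frame with one row per cell: id, type, volume, relative
#'   volume error, surface area, height, width, elongation and sphericity.
#' @export
measure_scene <- function(scene) {
  rows <- lapply(scene$cells, function(cell) {
    V <- signed_volume(cell)
    ext <- cell_extents(cell)
    data.frame(cell = cell$id, type = cell$type, volume = V,
               volume_error = (V - cell$V0) / cell$V0,
               area = surface_area(cell),
               height = ext$height, width = ext$width,
               elongation = ext$height / ext$width,
               sphericity = sphericity(cell))
  })
  do.call(rbind, rows)
}
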