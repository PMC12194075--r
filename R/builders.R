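#' Quasi-uniform cell centers on a sphere
#'
#' Deterministic generalized-spiral (Fibonacci) lattice: works for any
#' `n >= 2` and gives a near-constant nearest-neighbour spacing. Apical
#' axes point radially outward.
#'
#' @param n Number of cells, `>= 2`.
#' @param radius Sphere radius.
#' @return List with `centers` (n x 3) and `axes` (n x 3, outward unit).
#' @export
place_cells_on_sphere <- function(n, radius) {
  stopifnot(n >= 2, radius > 0)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  az <- i * pi * (3 - sqrt(5))   # golden angle
  rxy <- sqrt(pmax(0, 1 - z^2))
  axes <- cbind(rxy * cos(az), rxy * sin(az), z)
  list(centers = radius * axes, axes = axes)
}

#' Endodermal plate shape mask
#'
#' Declares the shape of the endodermal plate drawn around the oral pole.
#' `cap` is a polar-angle threshold; the other shapes are masks in the
#' azimuthal-equidistant chart around the pole (local coordinates
#' `theta * (cos phi, sin phi)` in radians).
#'
#' @param kind One of `"cap"`, `"rectangle"`, `"triangle"`, `"t_shape"`,
#'   `"star"`.
#' @param angle Cap polar-angle threshold (radians); `pi/3` selects about a
#'   quarter of the sphere's cells.
#' @param width,height Rectangle extent (radians in the chart).
#' @param size Circumradius of the triangle / outer radius of the star /
#'   overall extent of the T (radians).
#' @param inner Star inner-to-outer radius ratio.
#' @param points Number of star points.
#' @return An `mc_plate_shape`.
#' @export
plate_shape <- function(kind = c("cap", "rectangle", "triangle", "t_shape",
                                 "star"),
                        angle = pi / 3, width = 1.2, height = 0.6,
                        size = 1.0, inner = 0.45, points = 5) {
  kind <- match.arg(kind)
  structure(list(kind = kind, angle = angle, width = width, height = height,
                 size = size, inner = inner, points = points),
            class = "mc_plate_shape")
}

#' Select the endoderm cell set of a plate shape
#'
#' Cells whose centers fall inside the shape mask around the oral pole;
#' remaining cells are ectoderm. Errors if the mask selects no cell.
#'
#' @param centers Cell-center matrix (n x 3) on the sphere.
#' @param shape An [plate_shape()] object.
#' @param oral_axis Direction of the oral pole.
#' @return Integer vector of selected cell indices.
#' @export
select_plate <- function(centers, shape, oral_axis = c(0, 0, 1)) {
  stopifnot(inherits(shape, "mc_plate_shape"))
  u <- oral_axis / sqrt(sum(oral_axis^2))
  d <- centers / sqrt(rowSums(centers^2))
  ct <- pmin(1, pmax(-1, as.vector(d %*% u)))
  theta <- acos(ct)
  if (shape$kind == "cap") {
    sel <- which(theta <= shape$angle)
  } else {
    # azimuthal-equidistant chart around the oral pole
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    phi <- atan2(d %*% e2, d %*% e1)[, 1]
    a <- theta * cos(phi)
    b <- theta * sin(phi)
    poly <- shape_polygon(shape)
    sel <- which(point_in_polygon(a, b, poly$x, poly$y))
  }
  if (!length(sel)) stop("plate shape selects no cell")
  sel
}

shape_polygon <- function(shape) {
  switch(shape$kind,
    rectangle = {
      w <- shape$width / 2; h <- shape$height / 2
      list(x = c(-w, w, w, -w), y = c(-h, -h, h, h))
    },
    triangle = {
      ang <- pi / 2 + 2 * pi * (0:2) / 3
      list(x = shape$size * cos(ang), y = shape$size * sin(ang))
    },
    t_shape = {
      s <- shape$size
      # stem width s/3, bar height s/3, overall extent ~s x s
      list(x = c(-s / 6, s / 6, s / 6, s / 2, s / 2, -s / 2, -s / 2, -s / 6),
           y = c(-s / 2, -s / 2, s / 6, s / 6, s / 2, s / 2, s / 6, s / 6))
    },
    star = {
      k <- shape$points
      ang <- pi / 2 + pi * (0:(2 * k - 1)) / k
      r <- rep(c(shape$size, shape$size * shape$inner), k)
      list(x = r * cos(ang), y = r * sin(ang))
    },
    stop("no polygon for shape kind: ", shape$kind))
}

# even-odd rule point-in-polygon, vectorised over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Cell adjacency graph from center proximity
#'
#' Cells are adjacent when their center distance is below `factor` times
#' the mean nearest-neighbour distance. Robust to the irregular spacing of
#' spiral lattices and trimmed plates.
#'
#' @param centers Cell-center matrix (n x 3).
#' @param factor Distance multiplier (default 1.3).
#' @return Logical adjacency matrix (n x n, symmetric, FALSE diagonal).
#' @export
cell_adjacency <- function(centers, factor = 1.3) {
  n <- nrow(centers)
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  adj <- d < factor * mean(nn)
  diag(adj) <- FALSE
  adj
}

#' Decompose a plate into concentric rings
#'
#' Ring 0 is the single cell nearest the plate centroid (ties broken by
#' lowest cell id); ring `i` contains the plate cells at neighbour-graph
#' distance `i` from it (breadth-first search over the cell adjacency
#' graph). The rings partition the plate; a disconnected plate is rejected.
#'
#' @param centers Cell-center matrix of the whole scene.
#' @param plate Integer ids of the plate cells.
#' @param adjacency Optional precomputed adjacency matrix
#'   ([cell_adjacency()] of `centers` by default).
#' @return List of integer vectors, one per ring (innermost first).
#' @export
ring_decomposition <- function(centers, plate, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- cell_adjacency(centers)
  plate <- sort(unique(as.integer(plate)))
  ctr <- colMeans(centers[plate, , drop = FALSE])
  d2 <- rowSums(sweep(centers[plate, , drop = FALSE], 2, ctr, "-")^2)
  center_cell <- plate[which.min(d2)]   # which.min takes the first = lowest id

  dist <- rep(NA_integer_, nrow(centers))
  dist[center_cell] <- 0L
  frontier <- center_cell
  inplate <- logical(nrow(centers))
  inplate[plate] <- TRUE
  lvl <- 0L
  rings <- list(frontier)
  while (TRUE) {
    nxt <- integer(0)
    for (c_ in frontier) {
      nb <- which(adjacency[c_, ] & inplate & is.na(dist))
      dist[nb] <- lvl + 1L
      nxt <- c(nxt, nb)
    }
    nxt <- sort(unique(nxt))
    if (!length(nxt)) break
    lvl <- lvl + 1L
    rings[[lvl + 1L]] <- nxt
    frontier <- nxt
  }
  if (sum(lengths(rings)) != length(plate))
    stop("plate is not connected on the adjacency graph")
  rings
}

#' Constriction schedule for ring-decomposed plates
#'
#' Turns a ring decomposition into timed constriction events.
#' `simultaneous` starts every ring at `start`; `center_first` starts ring
#' `i` at `start + i * interval`; `edge_first` runs the ring order outermost
#' first.
#'
#' @param rings Ring list from [ring_decomposition()].
#' @param mode One of `"simultaneous"`, `"center_first"`, `"edge_first"`.
#' @param f_c Constriction factor.
#' @param start Time of the first event.
#' @param interval Time interval between consecutive rings.
#' @param band Constricting region band (percent).
#' @param ramp Per-event ramp duration.
#' @return List of `mc_event`s.
#' @export
constriction_schedule <- function(rings,
                                  mode = c("simultaneous", "center_first",
                                           "edge_first"),
                                  f_c = 0.1, start = 50, interval = 100,
                                  band = c(0, 50), ramp = 50) {
  mode <- match.arg(mode)
  if (interval < 0) stop("'interval' must be non-negative")
  nr <- length(rings)
  order_idx <- switch(mode,
    simultaneous = rep(0, nr),
    center_first = seq_len(nr) - 1,
    edge_first = rev(seq_len(nr)) - 1)
  lapply(seq_len(nr), function(i)
    constriction_event(rings[[i]], f_c = f_c, band = band,
                       start = start + order_idx[i] * interval, ramp = ramp))
}

#' Single free cell scene
#'
#' @param subdivisions Mesh subdivision level.
#' @param radius Cell radius.
#' @param k Uniform cortical stiffness.
#' @param params Scene parameters.
#' @return An `mc_scene` with one detached cell.
#' @export
build_single_cell <- function(subdivisions = 2L, radius = 1, k = 0.5,
                              params = default_params()) {
  mc_scene(list(icosphere(subdivisions, radius, k = k)), params = params)
}

#' Centered hexagonal disc lattice
#'
#' Cell centers of a hexagonally packed disc, ordered by (ring, angle).
#' Full discs have the centered-hexagonal counts 1 + 3r(r+1); a target
#' count below the next full-ring total is reached by removing
#' outermost-ring cells at evenly spaced angular positions (a deterministic
#' trimming rule).
#'
#' @param n Number of centers.
#' @param spacing Center-to-center distance.
#' @return Matrix (n x 2) of planar coordinates.
#' @export
hex_disc_centers <- function(n, spacing) {
  stopifnot(n >= 1)
  r <- 0L
  while (1 + 3 * r * (r + 1) < n) r <- r + 1L
  pts <- matrix(0, 1, 2)
  ring_id <- 0L
  for (q in seq_len(r)) {
    ring <- matrix(0, 0, 2)
    # walk the hexagonal ring of radius q
    ax <- c(q, 0)
    dirs <- matrix(c(-1, 1, -1, 0, 0, -1, 1, -1, 1, 0, 0, 1),
                   ncol = 2, byrow = TRUE)
    for (d_ in seq_len(6)) {
      for (s_ in seq_len(q)) {
        ring <- rbind(ring, ax)
        ax <- ax + dirs[d_, ]
      }
    }
    xy <- cbind(ring[, 1] + ring[, 2] / 2, ring[, 2] * sqrt(3) / 2)
    ang <- atan2(xy[, 2], xy[, 1])
    xy <- xy[order(ang), , drop = FALSE]
    pts <- rbind(pts, xy)
    ring_id <- c(ring_id, rep(q, nrow(xy)))
  }
  excess <- nrow(pts) - n
  if (excess > 0) {
    outer <- which(ring_id == r)
    if (excess > length(outer))
      stop("cannot trim ", excess, " cells from the outermost ring")
    drop <- outer[floor((seq_len(excess) - 1) * length(outer) / excess) + 1]
    pts <- pts[-drop, , drop = FALSE]
  }
  pts * spacing
}

#' Detached endodermal plate
#'
#' A hexagonally packed disc of adhered cells in the z = 0 plane with a
#' free boundary and no confinement; apical axes point up (+z). Full
#' hexagonal discs have 1 + 3r(r+1) cells (7, 19, 37, 61, 91, ...); other
#' counts are reached by trimming outermost-ring cells at evenly spaced
#' angular positions, so the 83-cell plate of the constriction-mode
#' experiments is the 91-cell disc minus 8 edge cells.
#'
#' @param n_cells Number of cells, `>= 7`.
#' @param subdivisions Cell mesh subdivision level.
#' @param radius Cell radius.
#' @param k Uniform cortical stiffness.
#' @param adhesion_band Adhesive region band (percent), default apico-lateral
#'   20--65%.
#' @param packing Center spacing as a fraction of the touching distance
#'   `2 * radius`.
#' @param params Scene parameters.
#' @return An `mc_scene`; the plate cell ids are all cells, the center
#'   roughly at the origin.
#' @export
build_detached_plate <- function(n_cells = 83L, subdivisions = 2L,
                                 radius = 1, k = 0.5,
                                 adhesion_band = c(20, 65),
                                 packing = 0.98,
                                 params = default_params()) {
  stopifnot(n_cells >= 7)
  xy <- hex_disc_centers(n_cells, packing * 2 * radius)
  cells <- lapply(seq_len(nrow(xy)), function(i) {
    cell <- icosphere(subdivisions, radius, center = c(xy[i, ], 0),
                      apical_axis = c(0, 0, 1), k = k, type = "endoderm",
                      id = i)
    cell$adhesive <- cell$band >= adhesion_band[1] &
      cell$band <= adhesion_band[2]
    cell
  })
  mc_scene(cells, params = params)
}

#' Hollow blastula of typed cells
#'
#' Places `n_cells` icosphere cells quasi-uniformly on a sphere (apical
#' axes outward), types them endoderm/ectoderm by the plate-shape mask
#' around the oral pole (+z), and assigns the per-type adhesive bands
#' (endoderm apico-lateral by default, ectoderm down to the basal pole).
#' The blastula radius is chosen so neighbouring cells touch at the given
#' packing fraction, which leaves the hollow blastocoel inside. Cells bond
#' to their neighbours during an initial equilibration phase; schedules
#' should therefore start no earlier than the scene's
#' `"equilibration"` attribute (50 time units by default).
#'
#' @param n_cells Number of cells (the experiments span 32--1024).
#' @param shape Plate-shape mask for the endoderm ([plate_shape()]).
#' @param subdivisions Cell mesh subdivision level.
#' @param cell_radius Cell radius.
#' @param k Uniform cortical stiffness.
#' @param endoderm_band,ectoderm_band Adhesive bands per type (percent).
#' @param packing Center spacing as a fraction of the touching distance.
#' @param params Scene parameters.
#' @return An `mc_scene` with attributes `"endoderm"` (plate cell ids),
#'   `"oral_axis"` and `"equilibration"`.
#' @export
build_blastula <- function(n_cells = 128L, shape = plate_shape("cap"),
                           subdivisions = 2L, cell_radius = 1, k = 0.5,
                           endoderm_band = c(20, 65),
                           ectoderm_band = c(20, 100),
                           packing = 0.98,
                           params = default_params()) {
  stopifnot(n_cells >= 2)
  R <- cell_radius * packing * sqrt(sqrt(3) * n_cells / (2 * pi))
  pl <- place_cells_on_sphere(n_cells, R)
  # spiral lattices are not perfectly uniform; if the tightest pair would
  # start deeply overlapping, shrink the cells to fit
  d <- as.matrix(stats::dist(pl$centers))
  diag(d) <- Inf
  min_nn <- min(d)
  if (min_nn < 1.2 * cell_radius) {
    cell_radius <- min_nn / 1.2
    warning("cells would initially overlap beyond tolerance; ",
            "cell radius reduced to ", signif(cell_radius, 4))
  }
  endo <- select_plate(pl$centers, shape, oral_axis = c(0, 0, 1))
  cells <- lapply(seq_len(n_cells), function(i) {
    type <- if (i %in% endo) "endoderm" else "ectoderm"
    band <- if (type == "endoderm") endoderm_band else ectoderm_band
    cell <- icosphere(subdivisions, cell_radius, center = pl$centers[i, ],
                      apical_axis = pl$axes[i, ], k = k, type = type, id = i)
    cell$adhesive <- cell$band >= band[1] & cell$band <= band[2]
    cell
  })
  scene <- mc_scene(cells, params = params)
  attr(scene, "endoderm") <- endo
  attr(scene, "oral_axis") <- c(0, 0, 1)
  attr(scene, "equilibration") <- 50
  scene
}

#' Planar ring of 3D cells between two confining plates
#'
#' Cells on a circle in the z = 0 plane, apical axes pointing radially
#' outward, held between two immovable plates a constant `gap` apart
#' (the planar cross-section experiment). A contiguous arc of
#' `n_endoderm` cells centered on the +x direction is typed endoderm.
#'
#' @param n_cells Cells on the circle, `>= 3`.
#' @param n_endoderm Endodermal arc length in cells.
#' @param subdivisions Cell mesh subdivision level.
#' @param cell_radius Cell radius.
#' @param gap Plate separation, `> 0` (slightly below the cell diameter so
#'   the plates keep the ring planar).
#' @param k Uniform cortical stiffness.
#' @param endoderm_band,ectoderm_band Adhesive bands per type.
#' @param packing Center spacing as a fraction of the touching distance.
#' @param plate_stiffness Confinement plane stiffness.
#' @param stiffness_zones List of `list(band =, k =)` entries applied to
#'   every cell ([set_region_stiffness()]); the default is the three-zone
#'   profile of the invagination experiments -- stiff apical (0--30%,
#'   k = 1), intermediate lateral (30--70%, k = 0.5), soft basal
#'   (70--100%, k = 0.1) -- under which constricting cells wedge and the
#'   arc folds deeply. `NULL` keeps the uniform stiffness `k`.
#' @param params Scene parameters. The planar experiment carries its own
#'   parameter table: a one-dimensional chain of cells has far fewer
#'   junctions per cell than a hexagonally packed sheet, so the per-bond
#'   pull defaults to `k_adh = 1.2` here (with sheet-level values the arc
#'   bends by only a fraction of a cell radius).
#' @return An `mc_scene` with attributes `"endoderm"`, `"oral_axis"`
#'   (+x, through the endoderm arc center) and `"equilibration"`.
#' @export
build_planar_scene <- function(n_cells = 64L, n_endoderm = 16L,
                               subdivisions = 2L, cell_radius = 1,
                               gap = 1.8, k = 0.5,
                               endoderm_band = c(20, 65),
                               ectoderm_band = c(20, 100),
                               packing = 0.98, plate_stiffness = 20,
                               stiffness_zones = list(
                                 list(band = c(0, 30), k = 1),
                                 list(band = c(30, 70), k = 0.5),
                                 list(band = c(70, 100), k = 0.1)),
                               params = default_params(k_adh = 1.2)) {
  stopifnot(n_cells >= 3, n_endoderm >= 1, n_endoderm <= n_cells)
  if (gap <= 0) stop("'gap' must be positive")
  Rc <- packing * n_cells * cell_radius / pi
  ang <- 2 * pi * (seq_len(n_cells) - 1) / n_cells
  # endodermal arc centered on angle 0: the n_endoderm cells closest to +x
  # by signed wrap-around index (positive side first on ties)
  rel <- ((seq_len(n_cells) - 1 + n_cells / 2) %% n_cells) - n_cells / 2
  endo <- sort(order(abs(rel), -sign(rel))[seq_len(n_endoderm)])
  cells <- lapply(seq_len(n_cells), function(i) {
    ax <- c(cos(ang[i]), sin(ang[i]), 0)
    type <- if (i %in% endo) "endoderm" else "ectoderm"
    band <- if (type == "endoderm") endoderm_band else ectoderm_band
    cell <- icosphere(subdivisions, cell_radius, center = Rc * ax,
                      apical_axis = ax, k = k, type = type, id = i)
    cell$adhesive <- cell$band >= band[1] & cell$band <= band[2]
    for (z in stiffness_zones)
      cell <- set_region_stiffness(cell, z$band, z$k)
    cell
  })
  planes <- list(
    confinement_plane(c(0, 0, gap / 2), c(0, 0, -1), plate_stiffness),
    confinement_plane(c(0, 0, -gap / 2), c(0, 0, 1), plate_stiffness))
  scene <- mc_scene(cells, planes = planes, params = params)
  attr(scene, "endoderm") <- endo
  attr(scene, "oral_axis") <- c(1, 0, 0)
  attr(scene, "equilibration") <- 50
  scene
}

#' Purse-string constriction events
#'
#' Constricts a sub-apical ring band (leaving the apical cap free, so the
#' apex stays convex) and pairs it with stiffness ramps on the apical cap
#' and the adjacent zone to counteract the outward volume pressure that
#' would otherwise balloon the apex.
#'
#' @param cells Target cell ids.
#' @param band Constricting sub-apical band; must not reach the apical
#'   pole.
#' @param f_c Constriction factor.
#' @param start Event start time.
#' @param ramp Ramp duration.
#' @param stiffening List of `list(band =, k =)` stiffness targets applied
#'   over the same window (defaults follow the purse-string protocol:
#'   apical cap 0--20% to k = 1.8, zone 20--60% to k = 1.4).
#' @return List of `mc_event`s.
#' @export
purse_string_events <- function(cells, band = c(20, 40), f_c = 0.1,
                                start = 50, ramp = 50,
                                stiffening = list(
                                  list(band = c(0, 20), k = 1.8),
                                  list(band = c(20, 60), k = 1.4))) {
  if (band[1] <= 0)
    stop("purse-string band must lie strictly below the apical pole")
  ev <- list(constriction_event(cells, f_c = f_c, band = band,
                                start = start, ramp = ramp))
  for (s in stiffening)
    ev <- c(ev, list(stiffness_event(cells, k = s$k, band = s$band,
                                     start = start, ramp = ramp)))
  ev
}

#' Cell centers of a scene
#'
#' @param scene An `mc_scene`.
#' @param current If `TRUE`, centroids of the current vertex positions;
#'   otherwise the construction-time centers.
#' @return Matrix (n cells x 3).
#' @export
scene_centers <- function(scene, current = TRUE) {
  t(vapply(scene$cells, function(c)
    if (current) colMeans(c$positions) else c$center, numeric(3)))
}
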