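#' Default simulation parameters
#'
#' The global parameter set of a scene. Time stepping (`dt`, `damping`,
#' `mass`), the cortical strain factor `f_et`, volume stiffness `k_v`,
#' adhesion parameters (`k_adh`, `lin_length`, `connect_length`,
#' `adhesion_chance`, `break_chance` -- the chances are percentages applied
#' per bond-update step), collision constant `k_col`, the AABB inflation
#' margin (floored at `connect_length` so the broad phase also serves the
#' adhesion search) and the bond/collision update strides. All values are
#' model units; see the methods vignette for how the defaults were chosen.
#'
#' @param ... Named overrides of individual defaults; unknown names error.
#' @return Named list of parameters.
#' @export
default_params <- function(...) {
  p <- list(
    dt = 0.05,
    damping = 0.2,
    mass = 1,
    f_et = 0.8,
    k_v = 50,
    volume_weighting = "area",
    k_adh = 0.4,
    lin_length = 0.1,
    connect_length = 0.45,
    adhesion_chance = 60,
    break_chance = 0.2,
    k_col = 10,
    aabb_margin = 0.45,
    bond_stride = 1L,
    collision_stride = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  if (p$aabb_margin < p$connect_length) p$aabb_margin <- p$connect_length
  if (!p$volume_weighting %in% c("area", "uniform"))
    stop("'volume_weighting' must be \"area\" or \"uniform\"")
  stopifnot(p$dt > 0, p$damping >= 0, p$damping <= 1, p$mass > 0,
            p$f_et > 0, p$f_et <= 1, p$k_v >= 0, p$lin_length > 0,
            p$lin_length <= p$connect_length,
            p$adhesion_chance >= 0, p$adhesion_chance <= 100,
            p$break_chance >= 0, p$break_chance <= 100)
  p
}

#' Static confinement plane
#'
#' An immovable half-space boundary: vertices that cross to the negative
#' side of the plane normal receive a restoring force of
#' `stiffness * depth` along the normal. Used in planar experiments to hold
#' a ring of 3D cells between two plates at constant distance.
#'
#' @param point A point on the plane.
#' @param normal Plane normal; the allowed side is the positive side.
#' @param stiffness Restoring force per unit penetration depth.
#' @return A `mc_plane` list.
#' @export
confinement_plane <- function(point, normal, stiffness = 20) {
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("'normal' must be non-zero")
  structure(list(point = as.numeric(point), normal = as.numeric(normal) / nn,
                 stiffness = stiffness), class = "mc_plane")
}

#' Assemble a scene from cells
#'
#' A scene bundles the cells, static confinement planes, global parameters,
#' the current adhesion-bond table and the integrator state (current time
#' and previous vertex positions; a fresh scene starts at rest).
#'
#' @param cells List of `mc_cell` objects (ids are renumbered 1..n).
#' @param planes List of `mc_plane` objects.
#' @param params Parameter list from [default_params()].
#' @return An object of class `mc_scene`.
#' @export
mc_scene <- function(cells, planes = list(), params = default_params()) {
  stopifnot(length(cells) >= 1)
  for (i in seq_along(cells)) {
    cells[[i]]$id <- i
    validate_mesh(cells[[i]])
  }
  structure(list(
    cells = cells,
    planes = planes,
    params = params,
    bonds = empty_bonds(),
    time = 0,
    prev = NULL
  ), class = "mc_scene")
}

empty_bonds <- function() {
  data.frame(cell_a = integer(), vertex_a = integer(),
             cell_b = integer(), vertex_b = integer())
}

#' @export
print.mc_scene <- function(x, ...) {
  nv <- sum(vapply(x$cells, function(c) nrow(c$positions), 1L))
  types <- table(vapply(x$cells, function(c) c$type, ""))
  cat(sprintf("<mc_scene> %d cell(s) (%s), %d vertices, %d plane(s)\n",
              length(x$cells),
              paste(sprintf("%s: %d", names(types), types), collapse = ", "),
              nv, length(x$planes)))
  cat(sprintf("  t = %g, %d adhesion bond(s)\n", x$time, nrow(x$bonds)))
  invisible(x)
}

#' @export
summary.mc_scene <- function(object, ...) {
  m <- measure_scene(object)
  print(object)
  print(m)
  invisible(m)
}

# --- flattening for the compiled core ---------------------------------------

# Global vertex/edge offsets; cells occupy contiguous index ranges so faces
# and edges can be grouped per cell without reordering.
scene_offsets <- function(scene) {
  nv <- vapply(scene$cells, function(c) nrow(c$positions), 1L)
  ne <- vapply(scene$cells, function(c) nrow(c$edges), 1L)
  list(nv = nv, ne = ne,
       voff = cumsum(c(0L, nv[-length(nv)])),
       eoff = cumsum(c(0L, ne[-length(ne)])))
}

scene_pack <- function(scene, events = list()) {
  off <- scene_offsets(scene)
  cells <- scene$cells
  pos <- do.call(rbind, lapply(cells, function(c) c$positions))
  prev <- if (is.null(scene$prev)) pos else
    do.call(rbind, scene$prev)
  edges <- do.call(rbind, lapply(seq_along(cells), function(i)
    cells[[i]]$edges + off$voff[i]))
  faces <- do.call(rbind, lapply(seq_along(cells), function(i)
    cells[[i]]$faces + off$voff[i]))
  face_cell <- rep(seq_along(cells) - 1L,
                   vapply(cells, function(c) nrow(c$faces), 1L))

  partner <- rep(-1L, nrow(pos))
  if (nrow(scene$bonds)) {
    ga <- off$voff[scene$bonds$cell_a] + scene$bonds$vertex_a
    gb <- off$voff[scene$bonds$cell_b] + scene$bonds$vertex_b
    partner[ga] <- gb - 1L
    partner[gb] <- ga - 1L
  }

  ev <- sort_events(events)
  ev_edges <- integer(0)
  ev_ptr <- 0L
  for (e in ev) {
    ge <- integer(0)
    for (ci in e$cells) {
      sel <- select_region(cells[[ci]], e$band)
      ge <- c(ge, sel$edges + off$eoff[ci])
    }
    ev_edges <- c(ev_edges, ge - 1L)
    ev_ptr <- c(ev_ptr, length(ev_edges))
  }

  planes <- scene$planes
  np <- length(planes)
  plane_point <- matrix(0, np, 3)
  plane_normal <- matrix(0, np, 3)
  plane_k <- numeric(np)
  for (i in seq_len(np)) {
    plane_point[i, ] <- planes[[i]]$point
    plane_normal[i, ] <- planes[[i]]$normal
    plane_k[i] <- planes[[i]]$stiffness
  }

  list(
    pos = pos, prev = prev,
    cell_start = as.integer(off$voff),
    cell_nv = as.integer(off$nv),
    edges = edges - 1L,
    edge_k = unlist(lapply(cells, function(c) c$k), use.names = FALSE),
    edge_lrest = unlist(lapply(cells, function(c) c$l_rest), use.names = FALSE),
    edge_l0 = unlist(lapply(cells, function(c) c$l0), use.names = FALSE),
    faces = faces - 1L,
    face_cell = face_cell,
    V0 = vapply(cells, function(c) c$V0, 1),
    adhesive = as.integer(unlist(lapply(cells, function(c) c$adhesive),
                                 use.names = FALSE)),
    bond_partner = partner,
    params = scene$params,
    plane_point = plane_point, plane_normal = plane_normal, plane_k = plane_k,
    ev_type = vapply(ev, function(e) if (e$type == "constriction") 0L else 1L, 1L),
    ev_start = vapply(ev, function(e) as.numeric(e$start), 1),
    ev_ramp = vapply(ev, function(e) as.numeric(e$ramp), 1),
    ev_value = vapply(ev, function(e) as.numeric(e$value), 1),
    ev_ptr = as.integer(ev_ptr),
    ev_edges = as.integer(ev_edges)
  )
}

# ascending start time so the latest-started event wins on shared edges
sort_events <- function(events) {
  if (!length(events)) return(list())
  for (e in events) {
    if (!inherits(e, "mc_event")) stop("events must be 'mc_event' objects")
  }
  events[order(vapply(events, function(e) as.numeric(e$start), 1))]
}

# write flattened state back into the scene
scene_unpack <- function(scene, res) {
  off <- scene_offsets(scene)
  for (i in seq_along(scene$cells)) {
    vidx <- off$voff[i] + seq_len(off$nv[i])
    eidx <- off$eoff[i] + seq_len(off$ne[i])
    scene$cells[[i]]$positions <- res$pos[vidx, , drop = FALSE]
    scene$cells[[i]]$l0 <- res$edge_l0[eidx]
    scene$cells[[i]]$k <- res$edge_k[eidx]
  }
  scene$prev <- lapply(seq_along(scene$cells), function(i)
    res$prev[off$voff[i] + seq_len(off$nv[i]), , drop = FALSE])
  scene$bonds <- partner_to_bonds(res$bond_partner, off)
  scene$time <- res$t
  scene
}

partner_to_bonds <- function(partner, off) {
  ga <- which(partner > seq_along(partner) - 1L)  # canonical end: partner > self
  if (!length(ga)) return(empty_bonds())
  gb <- partner[ga] + 1L
  cell_of <- function(g) findInterval(g - 1L, off$voff)
  ca <- cell_of(ga)
  cb <- cell_of(gb)
  data.frame(cell_a = ca, vertex_a = ga - off$voff[ca],
             cell_b = cb, vertex_b = gb - off$voff[cb])
}

#' Per-vertex forces of a scene, split by module
#'
#' Evaluates one force pass at the scene's current state and time:
#' cortical elastic, volume conservation, adhesion (current bond table),
#' collision and plane confinement, plus their sum. No integration and no
#' bond turnover happens.
#'
#' @param scene An `mc_scene`.
#' @param events Optional list of `mc_event`s in force at `scene$time`.
#' @return List of (total vertices x 3) matrices: `elastic`, `volume`,
#'   `adhesion`, `collision`, `confinement`, `total`.
#' @export
scene_forces <- function(scene, events = list()) {
  forces_core(scene_pack(scene, events), scene$time)
}

#' Detected vertex-through-face penetrations
#'
#' Runs the AABB broad phase and the vertex-triangle narrow phase on the
#' scene's current positions. A contact is a vertex of one cell whose
#' nearest-feature signed distance to another cell's boundary is negative;
#' it is reported with the violated face, perpendicular penetration depth
#' and the barycentric weights of the foot point.
#'
#' @param scene An `mc_scene`.
#' @return Data frame with columns `cell`, `vertex`, `violated_cell`,
#'   `face`, `depth`, `w1`, `w2`, `w3`.
#' @export
find_contacts <- function(scene) {
  contacts_core(scene_pack(scene))
}

#' Candidate cell pairs from the AABB broad phase
#'
#' Pairs of cells whose axis-aligned bounding boxes, inflated by the scene's
#' margin (at least the adhesion connect length), overlap. Guaranteed to
#' contain every pair in actual penetration or adhesion range.
#'
#' @param scene An `mc_scene`.
#' @return Two-column integer matrix of cell id pairs.
#' @export
broad_phase <- function(scene) {
  broad_phase_core(scene_pack(scene))
}
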