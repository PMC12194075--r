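#' Nonlinear cortical elastic force
#'
#' Signed force magnitude of a cortical elastic element with
#' length-dependent stiffness, `F = -(k / l0) x^2 - k x` with extension
#' `x = l - l0`. Negative values pull the edge's endpoints together,
#' positive values push them apart. The quadratic term makes stretching
#' harder than compression (strain stiffening); the response crosses zero
#' again at `x = -l0`, and beyond that point (edge shorter than the zero of
#' the response) the force is clamped to zero rather than allowed to turn
#' anti-restorative.
#'
#' @param k Elastic constant (stiffness), `k >= 0`.
#' @param l Current element length.
#' @param l0 Rest length, must be positive.
#' @return Signed force magnitude along the edge direction (vectorised).
#' @examples
#' elastic_force(0.5, 1.2, 1)   # -0.12, pulls together
#' elastic_force(0.5, 0.8, 1)   #  0.08, pushes apart
#' @export
elastic_force <- function(k, l, l0) {
  if (any(l0 <= 0)) stop("'l0' must be positive")
  x <- l - l0
  out <- -(k / l0) * x^2 - k * x
  out[x < -l0] <- 0
  out
}

#' Constant-force adhesion bond magnitude
#'
#' Force with which two bonded vertices are pulled together: linear in the
#' separation below `lin_length` (`k_adh * l / lin_length`) and constant
#' `k_adh` above it. The linear ramp near the zero-separation target keeps
#' the force continuous and avoids on/off "bouncing" of adhered cells; both
#' branches agree at `l = lin_length`.
#'
#' @param l Separation distance, `l >= 0` (vectorised).
#' @param k_adh Pull strength of the bond.
#' @param lin_length Linear-ramp cutoff distance, `0 < lin_length`.
#' @return Non-negative attraction magnitude.
#' @export
adhesion_force <- function(l, k_adh, lin_length) {
  if (lin_length <= 0) stop("'lin_length' must be positive")
  ifelse(l <= lin_length, k_adh * l / lin_length, k_adh)
}

#' Rest-length multiplier of a constriction event
#'
#' Linear ramp from 1 (before the event starts) to the constriction factor
#' `f_c` (from `start + ramp` onward). A ramp of zero switches instantly.
#'
#' @param t Simulation time (vectorised).
#' @param f_c Constriction factor in (0, 1].
#' @param start Event start time.
#' @param ramp Ramp duration (time units), `>= 0`.
#' @return Multiplier applied to the strained rest length of the event's
#'   edges (`l0 = multiplier * f_et * l_rest`).
#' @export
constriction_multiplier <- function(t, f_c, start, ramp) {
  frac <- if (ramp > 0) pmin(1, pmax(0, (t - start) / ramp)) else
    as.numeric(t >= start)
  1 + frac * (f_c - 1)
}

#' Stiffness value under a ramped stiffness event
#'
#' Linear interpolation from the stiffness at event start to the target,
#' reaching the target at `start + ramp`.
#'
#' @param t Simulation time (vectorised).
#' @param k_from Stiffness at event start.
#' @param k_to Target stiffness, `>= 0`.
#' @inheritParams constriction_multiplier
#' @return Interpolated stiffness.
#' @export
stiffness_at <- function(t, k_from, k_to, start, ramp) {
  if (k_to < 0) stop("target stiffness must be non-negative")
  frac <- if (ramp > 0) pmin(1, pmax(0, (t - start) / ramp)) else
    as.numeric(t >= start)
  k_from + frac * (k_to - k_from)
}

#' Volume-conservation force of one cell
#'
#' Reference implementation of the per-vertex volume restoring force with
#' magnitude `k_v * |V - V0| / V0`, directed along the outward vertex
#' normal when the cell is under volume (`V < V0`, inflate) and along the
#' inward normal when over volume (deflate). With `weighting = "uniform"`
#' every vertex receives exactly that magnitude; with the default
#' `weighting = "area"` each vertex is scaled by its share of the surface
#' area vector (mean scale 1), which makes the forces of a closed cell sum
#' to exactly zero -- the behaviour of a true pressure force, and what the
#' simulation core uses by default (see the methods vignette).
#'
#' @param cell An `mc_cell` (current positions; `V0` stored).
#' @param k_v Volume stiffness, `>= 0`.
#' @param weighting `"area"` (momentum-conserving, core default) or
#'   `"uniform"` (same magnitude on every vertex).
#' @return Numeric matrix (n x 3) of per-vertex forces.
#' @export
volume_force <- function(cell, k_v, weighting = c("area", "uniform")) {
  weighting <- match.arg(weighting)
  V <- signed_volume(cell)
  if (V <= 0) stop("mesh inversion: non-positive cell volume")
  s <- (V - cell$V0) / cell$V0
  if (weighting == "uniform") return(-k_v * s * vertex_normals(cell))
  pos <- cell$positions
  F <- cell$faces
  a <- pos[F[, 1], , drop = FALSE]
  n <- .rowcross(pos[F[, 2], , drop = FALSE] - a,
                 pos[F[, 3], , drop = FALSE] - a)
  G <- matrix(0, nrow(pos), 3)
  for (j in 1:3)
    for (d in 1:3)
      G[, d] <- G[, d] + tapply_add(F[, j], n[, d] / 2, nrow(pos))
  abar <- mean(sqrt(rowSums(G^2)))
  -k_v * s / abar * G
}

#' Apply cortical strain to a cell's rest lengths
#'
#' Factorises every edge rest length as `l0 = f_et * l_rest`. Because the
#' conserved volume prevents the cortex from actually shrinking, the edges
#' stay stretched (`l > l0`) and the cortex keeps a constant tension, which
#' smooths the surface the way a real cell removes excess cortical
#' material. During a run the integrator re-applies this factorisation every
#' step (constriction events then override their own edge sets).
#'
#' @param cell An `mc_cell`.
#' @param f_et Cortical strain factor in (0, 1].
#' @return The cell with updated `l0`.
#' @export
apply_cortical_strain <- function(cell, f_et) {
  if (!(f_et > 0 && f_et <= 1)) stop("'f_et' must be in (0, 1]")
  cell$l0 <- f_et * cell$l_rest
  cell
}

#' One position-Verlet step with viscous damping
#'
#' `x_new = (2 - c) x - (1 - c) x_prev + a dt^2`, the damped Verlet update
#' used by the simulation core. With `c = 0` this is standard Verlet; with
#' `c = 1` the inherited velocity is fully damped each step.
#'
#' @param x Current positions (matrix or vector).
#' @param x_prev Previous positions.
#' @param a Accelerations (force / mass), same shape.
#' @param dt Time step.
#' @param damping Viscous damping factor `c` in \[0, 1\].
#' @return Updated positions.
#' @export
verlet_step <- function(x, x_prev, a, dt, damping) {
  if (dt <= 0) stop("'dt' must be positive")
  if (damping < 0 || damping > 1) stop("'damping' must be in [0, 1]")
  (2 - damping) * x - (1 - damping) * x_prev + a * dt^2
}

#' Set the cortical stiffness of a region band
#'
#' Static (construction-time) stiffness assignment: edges with both
#' endpoints in the band get stiffness `k`. Used to give cells non-uniform
#' stiffness profiles, e.g. a stiff apical zone (0--30%, k = 1), an
#' intermediate lateral zone (30--70%, k = 0.5) and a soft basal zone
#' (70--100%, k = 0.1). For stiffness changes during a run use
#' [stiffness_event()].
#'
#' @param cell An `mc_cell`.
#' @param band Region band (percent).
#' @param k Stiffness, `>= 0`.
#' @return The cell with updated edge stiffness.
#' @export
set_region_stiffness <- function(cell, band, k) {
  if (k < 0) stop("'k' must be non-negative")
  sel <- select_region(cell, band)
  cell$k[sel$edges] <- k
  cell
}

#' Timed constriction event
#'
#' Declares that, from `start` on, the edges of `band` in the listed cells
#' ramp their rest length down to `f_c` times the strained baseline over
#' `ramp` time units. Overlapping events on the same edge are resolved
#' latest-start-wins.
#'
#' @param cells Integer vector of target cell ids.
#' @param f_c Constriction factor in (0, 1].
#' @param band Region band (percent of polar arc) whose edges constrict.
#' @param start Start time (time units).
#' @param ramp Ramp duration (time units).
#' @return An `mc_event` of type `"constriction"`.
#' @export
constriction_event <- function(cells, f_c, band = c(0, 50), start = 0,
                               ramp = 50) {
  if (!(f_c > 0 && f_c <= 1)) stop("'f_c' must be in (0, 1]")
  if (ramp < 0) stop("'ramp' must be non-negative")
  structure(list(type = "constriction", cells = as.integer(cells),
                 band = band, value = f_c, start = start, ramp = ramp),
            class = "mc_event")
}

#' Timed stiffness event
#'
#' Ramps the stiffness of the edges of `band` in the listed cells linearly
#' from their value at `start` to `k` over `ramp` time units.
#'
#' @param cells Integer vector of target cell ids.
#' @param k Target stiffness, `>= 0`.
#' @inheritParams constriction_event
#' @return An `mc_event` of type `"stiffness"`.
#' @export
stiffness_event <- function(cells, k, band = c(0, 100), start = 0,
                            ramp = 50) {
  if (k < 0) stop("target stiffness 'k' must be non-negative")
  if (ramp < 0) stop("'ramp' must be non-negative")
  structure(list(type = "stiffness", cells = as.integer(cells),
                 band = band, value = k, start = start, ramp = ramp),
            class = "mc_event")
}

#' @export
print.mc_event <- function(x, ...) {
  cat(sprintf("<mc_event %s> %d cell(s), band %g-%g%%, value %g, t = %g (+%g ramp)\n",
              x$type, length(x$cells), x$band[1], x$band[2], x$value,
              x$start, x$ramp))
  invisible(x)
}
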