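#' Run the simulation
#'
#' Advances a scene to `end_time` with the damped Verlet scheme. Each step:
#' due schedule events are applied (cortical strain baseline, constriction
#' and stiffness ramps), cell bounding boxes are refreshed, adhesion bonds
#' break and form stochastically, all forces are accumulated (elastic,
#' volume, adhesion, collision, confinement), positions are integrated, and
#' at the recording stride a snapshot with per-cell volumes, bond count and
#' a kinetic proxy is stored. The simulation clock advances by `dt` per
#' step. Runs are fully reproducible: with the same scene, events and seed
#' the measurement stream is bit-identical.
#'
#' On mesh inversion (a cell volume reaching zero) or a non-finite force the
#' run aborts with a warning naming the cause; the returned object then
#' carries the last good state and `ok = FALSE`.
#'
#' @param scene An `mc_scene` (fresh, or mid-run to continue).
#' @param events List of `mc_event` objects.
#' @param end_time Simulation time to advance to (must exceed `scene$time`).
#' @param record_every Recording cadence in time units.
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the stochastic bond turnover is reproducible.
#' @return An `mc_run` with elements `scene` (final state), `ok`,
#'   `times`, `snapshots` (list of global vertex-position matrices),
#'   `volumes` (recorded steps x cells), `bond_counts`, `kinetic`,
#'   `measurements` (per-cell shape metrics per recorded step) and
#'   `events`.
#' @export
run_simulation <- function(scene, events = list(), end_time,
                           record_every = 5, seed = NULL) {
  stopifnot(inherits(scene, "mc_scene"))
  if (end_time <= scene$time)
    stop("'end_time' must exceed the scene's current time")
  if (!is.null(seed)) set.seed(seed)

  p <- scene$params
  nsteps <- as.integer(round((end_time - scene$time) / p$dt))
  record_stride <- max(1L, as.integer(round(record_every / p$dt)))

  pack <- scene_pack(scene, events)
  res <- simulate_core(pack, scene$time, nsteps, record_stride,
                       as.integer(p$bond_stride),
                       as.integer(p$collision_stride))
  if (!res$ok)
    warning("simulation aborted at t = ", res$t, ": ", res$abort_reason)

  scene <- scene_unpack(scene, res)
  run <- structure(list(
    scene = scene,
    ok = res$ok,
    abort_reason = if (res$ok) NULL else res$abort_reason,
    times = res$rec_time,
    snapshots = res$rec_pos,
    volumes = res$rec_volume,
    bond_counts = res$rec_bonds,
    kinetic = res$rec_kinetic,
    events = events
  ), class = "mc_run")
  run$measurements <- run_measurements(run)
  run
}

#' Reconstruct the scene at a recorded step
#'
#' @param run An `mc_run`.
#' @param i Recorded-step index (defaults to the last).
#' @return An `mc_scene` with the positions of snapshot `i`. Rest lengths,
#'   stiffness and bonds are those of the final state (they are not
#'   re-recorded per step).
#' @export
snapshot_scene <- function(run, i = length(run$times)) {
  stopifnot(inherits(run, "mc_run"), i >= 1, i <= length(run$times))
  scene <- run$scene
  off <- scene_offsets(scene)
  pos <- run$snapshots[[i]]
  for (ci in seq_along(scene$cells))
    scene$cells[[ci]]$positions <-
      pos[off$voff[ci] + seq_len(off$nv[ci]), , drop = FALSE]
  scene$time <- run$times[i]
  scene$prev <- NULL
  scene
}

# per-cell shape metrics for every recorded snapshot
run_measurements <- function(run) {
  scene <- run$scene
  ncell <- length(scene$cells)
  nrec <- length(run$times)
  if (nrec == 0) return(NULL)
  off <- scene_offsets(scene)
  out <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    pos <- run$snapshots[[r]]
    height <- width <- area <- numeric(ncell)
    for (ci in seq_len(ncell)) {
      cell <- scene$cells[[ci]]
      cell$positions <- pos[off$voff[ci] + seq_len(off$nv[ci]), , drop = FALSE]
      ext <- cell_extents(cell)
      height[ci] <- ext$height
      width[ci] <- ext$width
      area[ci] <- surface_area(cell)
    }
    out[[r]] <- data.frame(
      time = run$times[r],
      cell = seq_len(ncell),
      type = vapply(scene$cells, function(c) c$type, ""),
      volume = run$volumes[r, ],
      area = area,
      height = height,
      width = width,
      elongation = height / width,
      bonds = run$bond_counts[r],
      kinetic = run$kinetic[r])
  }
  do.call(rbind, out)
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("<mc_run> %s, t = %g, %d recorded step(s), %d cell(s)\n",
              if (x$ok) "completed" else
                paste0("ABORTED (", x$abort_reason, ")"),
              x$scene$time, length(x$times), length(x$scene$cells)))
  if (length(x$times)) {
    verr <- max(abs(sweep(x$volumes, 2,
                          vapply(x$scene$cells, function(c) c$V0, 1),
                          "-")) /
                rep(vapply(x$scene$cells, function(c) c$V0, 1),
                    each = nrow(x$volumes)))
    cat(sprintf("  max |V - V0| / V0 over run: %.3g; final bonds: %d\n",
                verr, x$bond_counts[length(x$bond_counts)]))
  }
  invisible(x)
}

#' Diagnostic plots of a run
#'
#' Four base-graphics panels: relative volume error per cell, bond count,
#' kinetic proxy (sum of squared per-step displacements, log scale) and
#' cell elongation over time.
#'
#' @param x An `mc_run`.
#' @param ... Unused.
#' @export
plot.mc_run <- function(x, ...) {
  if (!length(x$times)) {
    warning("no recorded steps to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  V0 <- vapply(x$scene$cells, function(c) c$V0, 1)
  rel <- sweep(sweep(x$volumes, 2, V0, "-"), 2, V0, "/")
  graphics::matplot(x$times, rel, type = "l", lty = 1,
                    xlab = "time", ylab = "(V - V0) / V0",
                    main = "volume conservation")
  graphics::plot(x$times, x$bond_counts, type = "l",
                 xlab = "time", ylab = "bonds", main = "adhesion bonds")
  graphics::plot(x$times, pmax(x$kinetic, 1e-300), type = "l", log = "y",
                 xlab = "time", ylab = "sum |dx|^2", main = "kinetic proxy")
  m <- x$measurements
  el <- matrix(m$elongation, nrow = length(x$times), byrow = TRUE)
  graphics::matplot(x$times, el, type = "l", lty = 1,
                    xlab = "time", ylab = "height / width",
                    main = "cell elongation")
  invisible(x)
}
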