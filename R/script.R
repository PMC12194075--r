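#' Parse an experiment script
#'
#' Experiments are declared in a YAML document with four top-level
#' sections: `scene` (builder and its arguments), `params` (overrides of
#' [default_params()]), run controls (`seed`, `end_time`, `record_every`),
#' an `events` table and an optional `output` section. Parsing is strict:
#' unknown keys, unknown builders or modes, malformed bands and negative
#' event times are rejected with an error naming the offending field, and
#' all defaults are resolved at parse time so the run manifest echoes the
#' complete configuration.
#'
#' Event entries either target cells directly
#' (`type: constriction | stiffness`, `cells: endoderm | all | [ids]`)
#' or expand a ring-constriction schedule
#' (`type: ring_constriction`, `mode: simultaneous | center_first |
#' edge_first`, `interval`, `f_c`).
#'
#' @param text Script text, or a file path when `is_path = TRUE`.
#' @param is_path Treat `text` as a file path.
#' @return An `mc_script` object.
#' @export
parse_script <- function(text, is_path = FALSE) {
  raw <- tryCatch(
    if (is_path) yaml::read_yaml(text) else yaml::yaml.load(text),
    error = function(e) stop("script is not valid YAML: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("script must be a YAML mapping")

  known_top <- c("scene", "params", "seed", "end_time", "record_every",
                 "events", "output")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    stop("unknown top-level field(s): ", paste(bad, collapse = ", "))

  sc <- raw$scene
  if (is.null(sc) || is.null(sc$builder))
    stop("field 'scene.builder' is required")
  builders <- c("single_cell", "detached_plate", "planar_ring", "blastula")
  if (!sc$builder %in% builders)
    stop("unknown builder in field 'scene.builder': '", sc$builder, "'")

  allowed_args <- list(
    single_cell = c("subdivisions", "radius", "k"),
    detached_plate = c("n_cells", "subdivisions", "radius", "k",
                       "adhesion_band", "packing"),
    planar_ring = c("n_cells", "n_endoderm", "subdivisions", "cell_radius",
                    "gap", "k", "endoderm_band", "ectoderm_band", "packing",
                    "plate_stiffness"),
    blastula = c("n_cells", "plate_shape", "plate_angle", "plate_size",
                 "plate_width", "plate_height", "subdivisions",
                 "cell_radius", "k", "endoderm_band", "ectoderm_band",
                 "packing"))
  extra <- setdiff(names(sc), c("builder", allowed_args[[sc$builder]]))
  if (length(extra))
    stop("unknown field(s) in 'scene' for builder '", sc$builder, "': ",
         paste(extra, collapse = ", "))
  if (!is.null(sc$plate_shape) &&
      !sc$plate_shape %in% c("cap", "rectangle", "triangle", "t_shape",
                             "star"))
    stop("unknown plate shape in field 'scene.plate_shape': '",
         sc$plate_shape, "'")

  params <- tryCatch(do.call(default_params, as.list(raw$params)),
                     error = function(e)
                       stop("field 'params': ", conditionMessage(e),
                            call. = FALSE))

  events <- raw$events
  if (is.null(events)) events <- list()
  ev_known <- list(
    constriction = c("type", "cells", "band", "value", "f_c", "start",
                     "ramp"),
    stiffness = c("type", "cells", "band", "value", "k", "start", "ramp"),
    ring_constriction = c("type", "mode", "f_c", "interval", "band",
                          "start", "ramp"))
  for (i in seq_along(events)) {
    e <- events[[i]]
    where <- sprintf("events[%d]", i)
    if (is.null(e$type) || !e$type %in% names(ev_known))
      stop(where, ": unknown event type '", e$type %||% "<missing>", "'")
    bad <- setdiff(names(e), ev_known[[e$type]])
    if (length(bad))
      stop(where, ": unknown field(s): ", paste(bad, collapse = ", "))
    if (!is.null(e$start) && e$start < 0)
      stop(where, ".start: events before t = 0 are rejected")
    if (!is.null(e$band) && (length(e$band) != 2 || e$band[1] > e$band[2] ||
                             e$band[1] < 0 || e$band[2] > 100))
      stop(where, ".band: must be [start, end] within [0, 100]")
    if (e$type == "ring_constriction") {
      if (is.null(e$mode) ||
          !e$mode %in% c("simultaneous", "center_first", "edge_first"))
        stop(where, ".mode: unknown constriction mode '",
             e$mode %||% "<missing>", "'")
    } else {
      if (is.null(e$cells))
        stop(where, ".cells: required ('endoderm', 'all' or an id list)")
    }
  }

  out <- raw$output
  if (is.null(out)) out <- list()
  bad <- setdiff(names(out), c("snapshot_every", "format"))
  if (length(bad))
    stop("unknown field(s) in 'output': ", paste(bad, collapse = ", "))
  if (!is.null(out$format) && !out$format %in% c("obj", "vtk"))
    stop("field 'output.format': unknown format '", out$format, "'")

  structure(list(
    scene = sc,
    params = params,
    seed = raw$seed %||% 1L,
    end_time = raw$end_time %||% 200,
    record_every = raw$record_every %||% 5,
    events = events,
    output = list(snapshot_every = out$snapshot_every %||% 0,
                  format = out$format %||% "obj")
  ), class = "mc_script")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the scene an experiment script declares
#'
#' @param script An `mc_script`.
#' @return An `mc_scene`.
#' @export
script_scene <- function(script) {
  sc <- script$scene
  p <- script$params
  switch(sc$builder,
    single_cell = build_single_cell(
      subdivisions = sc$subdivisions %||% 2L,
      radius = sc$radius %||% 1,
      k = sc$k %||% 0.5, params = p),
    detached_plate = build_detached_plate(
      n_cells = sc$n_cells %||% 83L,
      subdivisions = sc$subdivisions %||% 2L,
      radius = sc$radius %||% 1, k = sc$k %||% 0.5,
      adhesion_band = unlist(sc$adhesion_band %||% c(20, 65)),
      packing = sc$packing %||% 0.98, params = p),
    planar_ring = build_planar_scene(
      n_cells = sc$n_cells %||% 64L,
      n_endoderm = sc$n_endoderm %||% 16L,
      subdivisions = sc$subdivisions %||% 2L,
      cell_radius = sc$cell_radius %||% 1,
      gap = sc$gap %||% 1.8, k = sc$k %||% 0.5,
      endoderm_band = unlist(sc$endoderm_band %||% c(20, 65)),
      ectoderm_band = unlist(sc$ectoderm_band %||% c(20, 100)),
      packing = sc$packing %||% 0.98,
      plate_stiffness = sc$plate_stiffness %||% 20, params = p),
    blastula = build_blastula(
      n_cells = sc$n_cells %||% 128L,
      shape = plate_shape(sc$plate_shape %||% "cap",
                          angle = sc$plate_angle %||% pi / 3,
                          size = sc$plate_size %||% 1.0,
                          width = sc$plate_width %||% 1.2,
                          height = sc$plate_height %||% 0.6),
      subdivisions = sc$subdivisions %||% 2L,
      cell_radius = sc$cell_radius %||% 1, k = sc$k %||% 0.5,
      endoderm_band = unlist(sc$endoderm_band %||% c(20, 65)),
      ectoderm_band = unlist(sc$ectoderm_band %||% c(20, 100)),
      packing = sc$packing %||% 0.98, params = p))
}

#' Expand an experiment script's event table against a scene
#'
#' @param script An `mc_script`.
#' @param scene The scene built by [script_scene()].
#' @return List of `mc_event`s.
#' @export
script_events <- function(script, scene) {
  endo <- attr(scene, "endoderm") %||% seq_along(scene$cells)
  out <- list()
  for (e in script$events) {
    if (e$type == "ring_constriction") {
      rings <- ring_decomposition(scene_centers(scene, current = FALSE),
                                  endo)
      out <- c(out, constriction_schedule(
        rings, mode = e$mode, f_c = e$f_c %||% 0.1,
        start = e$start %||% 50, interval = e$interval %||% 100,
        band = unlist(e$band %||% c(0, 50)), ramp = e$ramp %||% 50))
    } else {
      cells <- if (is.character(e$cells)) {
        switch(e$cells,
               endoderm = endo,
               all = seq_along(scene$cells),
               stop("unknown cell set token: '", e$cells, "'"))
      } else as.integer(unlist(e$cells))
      ev <- if (e$type == "constriction")
        constriction_event(cells, f_c = e$value %||% e$f_c %||% 0.1,
                           band = unlist(e$band %||% c(0, 50)),
                           start = e$start %||% 50, ramp = e$ramp %||% 50)
      else
        stiffness_event(cells, k = e$value %||% e$k %||% 0.5,
                        band = unlist(e$band %||% c(0, 100)),
                        start = e$start %||% 50, ramp = e$ramp %||% 50)
      out <- c(out, list(ev))
    }
  }
  out
}

#' Run an experiment script
#'
#' Builds the scene, expands the event table, runs the simulation and
#' writes the run products into `out_dir`: `measurements.csv` (the per-cell
#' measurement stream), `manifest.json` (complete resolved configuration,
#' seed, package version and event log), mesh snapshots at the configured
#' cadence, and `final_state.json` for restart.
#'
#' @param script An `mc_script` (or script text/path, passed through
#'   [parse_script()]).
#' @param out_dir Output directory.
#' @param seed Optional seed override.
#' @param end_time Optional end-time override.
#' @return The `mc_run`, invisibly.
#' @export
run_script <- function(script, out_dir, seed = NULL, end_time = NULL) {
  if (is.character(script))
    script <- parse_script(script, is_path = file.exists(script))
  stopifnot(inherits(script, "mc_script"))
  seed <- seed %||% script$seed
  end_time <- end_time %||% script$end_time
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scene <- script_scene(script)
  events <- script_events(script, scene)
  run <- run_simulation(scene, events, end_time = end_time,
                        record_every = script$record_every, seed = seed)

  utils::write.csv(run$measurements, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "morphocell",
    version = as.character(utils::packageVersion("morphocell")),
    seed = seed,
    end_time = end_time,
    record_every = script$record_every,
    steps_per_time_unit = 1 / script$params$dt,
    params = script$params,
    scene = script$scene,
    events = lapply(events, unclass),
    ok = run$ok,
    abort_reason = run$abort_reason)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (script$output$snapshot_every > 0) {
    snap_dir <- file.path(out_dir, "snapshots")
    every <- script$output$snapshot_every
    nextsnap <- -Inf
    for (i in seq_along(run$times)) {
      if (run$times[i] >= nextsnap) {
        write_snapshot(snapshot_scene(run, i), snap_dir,
                       format = script$output$format,
                       label = sprintf("t%09.2f", run$times[i]))
        nextsnap <- run$times[i] + every
      }
    }
  }
  save_scene(run$scene, file.path(out_dir, "final_state.json"))
  invisible(run)
}

#' Recompute shape metrics from a snapshot directory
#'
#' Reads every OBJ snapshot under `dir` and recomputes per-cell volume,
#' area and elongation offline.
#'
#' @param dir Snapshot directory written by [run_script()].
#' @return Data frame of per-snapshot, per-cell metrics.
#' @export
measure_snapshots <- function(dir) {
  files <- sort(list.files(dir, pattern = "^snapshot_.*\\.obj$",
                           full.names = TRUE))
  if (!length(files)) stop("no OBJ snapshots found under ", dir)
  rows <- lapply(files, function(f) {
    cells <- read_obj(f)
    do.call(rbind, lapply(cells, function(cl) {
      ctr <- colMeans(cl$positions)
      axis <- ctr - 0  # fallback axis: radial from origin
      if (sqrt(sum(axis^2)) < 1e-9) axis <- c(0, 0, 1)
      cell <- structure(list(positions = cl$positions, faces = cl$faces,
                             apical_axis = axis / sqrt(sum(axis^2))),
                        class = "mc_cell")
      ext <- cell_extents(cell)
      data.frame(file = basename(f), cell = cl$id, type = cl$type,
                 volume = signed_volume(cell),
                 area = surface_area(cell),
                 height = ext$height, width = ext$width,
                 elongation = ext$height / ext$width)
    }))
  })
  do.call(rbind, rows)
}
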