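#' Write a scene as Wavefront OBJ
#'
#' One `g cell_<id>` group per cell with global vertex numbering; cell type
#' and region band are carried as structured comments so the file round
#' trips through [read_obj()].
#'
#' @param scene An `mc_scene`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_obj <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# morphocell mesh snapshot", con)
  off <- 0L
  for (cell in scene$cells) {
    writeLines(sprintf("g cell_%d", cell$id), con)
    writeLines(sprintf("# celltype %d %s", cell$id, cell$type), con)
    writeLines(sprintf("v %.10g %.10g %.10g", cell$positions[, 1],
                       cell$positions[, 2], cell$positions[, 3]), con)
    writeLines(sprintf("f %d %d %d", cell$faces[, 1] + off,
                       cell$faces[, 2] + off, cell$faces[, 3] + off), con)
    off <- off + nrow(cell$positions)
  }
  invisible(path)
}

#' Read a Wavefront OBJ written by [write_obj()]
#'
#' @param path OBJ file path.
#' @return List of per-cell lists with `positions`, `faces` (local
#'   indexing), `type` and `id`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  cells <- list()
  cur <- NULL
  voff <- 0L
  types <- list()
  flush_cell <- function(cur, voff) {
    if (is.null(cur)) return(list(cells = cells, voff = voff))
    pos <- do.call(rbind, cur$v)
    faces <- do.call(rbind, cur$f) - voff
    cells[[length(cells) + 1L]] <<- list(positions = pos, faces = faces,
                                         id = cur$id, type = cur$type)
    list(voff = voff + nrow(pos))
  }
  for (ln in lines) {
    if (startsWith(ln, "g ")) {
      r <- flush_cell(cur, voff)
      if (!is.null(cur)) voff <- r$voff
      id <- as.integer(sub("^g cell_", "", ln))
      cur <- list(id = id, type = "cell", v = list(), f = list())
    } else if (startsWith(ln, "# celltype ")) {
      parts <- strsplit(trimws(sub("^# celltype ", "", ln)), " ")[[1]]
      cur$type <- parts[2]
    } else if (startsWith(ln, "v ")) {
      cur$v[[length(cur$v) + 1L]] <-
        as.numeric(strsplit(trimws(sub("^v ", "", ln)), " +")[[1]])
    } else if (startsWith(ln, "f ")) {
      cur$f[[length(cur$f) + 1L]] <-
        as.integer(strsplit(trimws(sub("^f ", "", ln)), " +")[[1]])
    }
  }
  flush_cell(cur, voff)
  cells
}

#' Write a scene as legacy VTK polydata
#'
#' ASCII legacy VTK with all cells' triangles and per-vertex scalars for
#' the region band coordinate, the cell id and the cell type (endoderm 1,
#' ectoderm 2, other 0).
#'
#' @param scene An `mc_scene`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_vtk <- function(scene, path) {
  pos <- do.call(rbind, lapply(scene$cells, function(c) c$positions))
  off <- scene_offsets(scene)
  faces <- do.call(rbind, lapply(seq_along(scene$cells), function(i)
    scene$cells[[i]]$faces + off$voff[i])) - 1L
  band <- unlist(lapply(scene$cells, function(c) c$band), use.names = FALSE)
  cid <- rep(seq_along(scene$cells), off$nv)
  tmap <- c(endoderm = 1L, ectoderm = 2L)
  tid <- rep(vapply(scene$cells, function(c) {
    v <- tmap[c$type]
    if (is.na(v)) 0L else as.integer(v)
  }, 1L), off$nv)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "morphocell snapshot", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pos))), con)
  writeLines(sprintf("%.10g %.10g %.10g", pos[, 1], pos[, 2], pos[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(faces), 4L * nrow(faces)), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(pos)),
               "SCALARS band double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", band), con)
  writeLines(c("SCALARS cell_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", cid), con)
  writeLines(c("SCALARS cell_type int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", tid), con)
  invisible(path)
}

#' Export the adhesion-bond table
#'
#' CSV with one row per bond: recording step/time, the two (cell, vertex)
#' endpoints and the current bond length.
#'
#' @param scene An `mc_scene`.
#' @param path Output CSV path.
#' @param step Step or time label stored in the first column.
#' @return Invisibly `path`.
#' @export
write_bonds_csv <- function(scene, path, step = scene$time) {
  b <- scene$bonds
  len <- if (nrow(b)) {
    pa <- t(vapply(seq_len(nrow(b)), function(i)
      scene$cells[[b$cell_a[i]]]$positions[b$vertex_a[i], ], numeric(3)))
    pb <- t(vapply(seq_len(nrow(b)), function(i)
      scene$cells[[b$cell_b[i]]]$positions[b$vertex_b[i], ], numeric(3)))
    sqrt(rowSums((pa - pb)^2))
  } else numeric(0)
  out <- cbind(step = rep(step, nrow(b)), b, length = len)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a mesh snapshot (plus bond table)
#'
#' @param scene An `mc_scene`.
#' @param dir Output directory (created if missing).
#' @param format `"obj"` or `"vtk"`.
#' @param label File name label (defaults to the scene time).
#' @return Invisibly the mesh file path.
#' @export
write_snapshot <- function(scene, dir, format = c("obj", "vtk"),
                           label = sprintf("t%09.2f", scene$time)) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh_path <- file.path(dir, sprintf("snapshot_%s.%s", label, format))
  if (format == "obj") write_obj(scene, mesh_path) else
    write_vtk(scene, mesh_path)
  write_bonds_csv(scene, file.path(dir, sprintf("bonds_%s.csv", label)))
  invisible(mesh_path)
}

#' Save the complete scene state for restart
#'
#' JSON serialisation of positions, previous positions (integrator state),
#' rest lengths, stiffness, bonds, types, bands, planes, parameters and the
#' simulation clock; [load_scene()] reconstructs a scene that continues a
#' run exactly where it stopped.
#'
#' @param scene An `mc_scene`.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
save_scene <- function(scene, path) {
  state <- list(
    time = scene$time,
    params = scene$params,
    planes = lapply(scene$planes, function(p)
      list(point = p$point, normal = p$normal, stiffness = p$stiffness)),
    bonds = as.list(scene$bonds),
    endoderm = attr(scene, "endoderm"),
    oral_axis = attr(scene, "oral_axis"),
    cells = lapply(scene$cells, function(c) list(
      id = c$id, type = c$type, V0 = c$V0, center = c$center,
      apical_axis = c$apical_axis, radius = c$radius,
      positions = c$positions, edges = c$edges, faces = c$faces,
      l_rest = c$l_rest, l0 = c$l0, k = c$k, band = c$band,
      adhesive = c$adhesive)),
    prev = scene$prev)
  jsonlite::write_json(state, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a scene saved with [save_scene()]
#'
#' @param path JSON path.
#' @return An `mc_scene`.
#' @export
load_scene <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  as_mat <- function(x, nc) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = nc, byrow = TRUE)
  }
  cells <- lapply(st$cells, function(cl) {
    structure(list(
      positions = as_mat(cl$positions, 3),
      edges = matrix(as.integer(as_mat(cl$edges, 2)), ncol = 2),
      faces = matrix(as.integer(as_mat(cl$faces, 3)), ncol = 3),
      l_rest = as.numeric(unlist(cl$l_rest)),
      l0 = as.numeric(unlist(cl$l0)),
      k = as.numeric(unlist(cl$k)),
      band = as.numeric(unlist(cl$band)),
      center = as.numeric(unlist(cl$center)),
      apical_axis = as.numeric(unlist(cl$apical_axis)),
      radius = cl$radius,
      V0 = cl$V0,
      type = cl$type,
      adhesive = as.logical(unlist(cl$adhesive)),
      id = as.integer(cl$id)), class = "mc_cell")
  })
  planes <- lapply(st$planes, function(p)
    confinement_plane(as.numeric(unlist(p$point)),
                      as.numeric(unlist(p$normal)), p$stiffness))
  bonds <- if (length(st$bonds) && length(st$bonds$cell_a))
    data.frame(cell_a = as.integer(unlist(st$bonds$cell_a)),
               vertex_a = as.integer(unlist(st$bonds$vertex_a)),
               cell_b = as.integer(unlist(st$bonds$cell_b)),
               vertex_b = as.integer(unlist(st$bonds$vertex_b)))
    else empty_bonds()
  scene <- structure(list(
    cells = cells, planes = planes,
    params = do.call(default_params, st$params),
    bonds = bonds,
    time = st$time,
    prev = if (is.null(st$prev)) NULL
      else if (is.array(st$prev) && length(dim(st$prev)) == 3)
        lapply(seq_len(dim(st$prev)[1]), function(i) st$prev[i, , ])
      else lapply(st$prev, function(m) as_mat(m, 3))),
    class = "mc_scene")
  if (!is.null(st$endoderm)) attr(scene, "endoderm") <- st$endoderm
  if (!is.null(st$oral_axis)) attr(scene, "oral_axis") <- st$oral_axis
  scene
}
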