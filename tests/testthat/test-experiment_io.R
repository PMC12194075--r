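test_that("experiment scripts parse, resolve defaults and reject bad tokens", {
  minimal <- "
scene:
  builder: single_cell
"
  sc <- parse_script(minimal)
  expect_s3_class(sc, "mc_script")
  scene <- script_scene(sc)
  expect_s3_class(scene, "mc_scene")
  expect_length(scene$cells, 1)
  expect_length(script_events(sc, scene), 0)

  full <- "
scene:
  builder: blastula
  n_cells: 16
  subdivisions: 1
params:
  f_et: 0.8
seed: 7
end_time: 120
events:
  - type: constriction
    cells: endoderm
    band: [0, 50]
    value: 0.1
    start: 50
    ramp: 50
"
  sc2 <- parse_script(full)
  scene2 <- script_scene(sc2)
  ev <- script_events(sc2, scene2)
  expect_length(ev, 1)
  expect_setequal(ev[[1]]$cells, attr(scene2, "endoderm"))
  expect_equal(ev[[1]]$value, 0.1)

  # a ring-constriction schedule expands into one event per ring, and the
  # simultaneous mode shares one start time
  ring <- parse_script("
scene:
  builder: blastula
  n_cells: 32
  subdivisions: 1
events:
  - type: ring_constriction
    mode: simultaneous
    f_c: 0.1
    band: [0, 50]
    start: 50
")
  scene3 <- script_scene(ring)
  ev3 <- script_events(ring, scene3)
  expect_gt(length(ev3), 1)
  expect_true(all(vapply(ev3, function(e) e$start, 1) == 50))
  expect_setequal(unlist(lapply(ev3, function(e) e$cells)),
                  attr(scene3, "endoderm"))

  # error contract: the offending token is named
  expect_error(parse_script("
scene:
  builder: blastul
"), "blastul")
  expect_error(parse_script("
scene:
  builder: blastula
events:
  - type: ring_constriction
    mode: centre_frist
"), "centre_frist")
  expect_error(parse_script("
scene:
  builder: blastula
  wobble: 3
"), "wobble")
  expect_error(parse_script("
scene:
  builder: blastula
events:
  - type: constriction
    cells: all
    start: -5
"), "t = 0")
})

test_that("cell elongation is 1 for spheres and tracks axis scaling", {
  cell <- icosphere(2)
  expect_equal(cell_elongation(cell), 1, tolerance = 0.02)
  tall <- cell
  tall$positions[, 3] <- 2 * tall$positions[, 3]   # prolate 2:1 along axis
  expect_equal(cell_elongation(tall), 2, tolerance = 0.05)
})

test_that("apical extents are isotropic on spheres and frame-consistent", {
  cell <- icosphere(2)   # apical axis +z
  ext <- apical_extents(cell, vertical = c(1, 0, 0), band = c(0, 20))
  expect_equal(unname(ext["vertical"] / ext["horizontal"]), 1,
               tolerance = 0.02)
  # squeezing the apical cap along x halves the vertical extent only
  squeezed <- cell
  squeezed$positions[, 1] <- 0.5 * squeezed$positions[, 1]
  ext2 <- apical_extents(squeezed, vertical = c(1, 0, 0), band = c(0, 20))
  expect_lt(ext2["vertical"] / ext2["horizontal"], 0.6)
  expect_error(apical_extents(cell, vertical = c(0, 0, 1)), "parallel")
})

test_that("invagination depth is zero at start and frame invariant", {
  scene <- build_blastula(16, subdivisions = 1)
  endo <- attr(scene, "endoderm")
  center_cell <- endo[1]
  expect_equal(invagination_depth(scene, scene, center_cell), 0)

  # rigid translation of the whole current scene does not register
  moved <- scene
  for (i in seq_along(moved$cells))
    moved$cells[[i]]$positions <-
      sweep(moved$cells[[i]]$positions, 2, c(3, -2, 5), "+")
  expect_equal(invagination_depth(moved, scene, center_cell), 0,
               tolerance = 1e-9)

  # artificially pushing the plate-center cell inward registers positively
  pushed <- scene
  pushed$cells[[center_cell]]$positions <-
    sweep(pushed$cells[[center_cell]]$positions, 2, c(0, 0, -0.5), "+")
  d <- invagination_depth(pushed, scene, center_cell)
  expect_gt(d, 0.4)
})

test_that("opening diameter: zero without a fold, 2R for a hemispherical cup", {
  # pre-invagination blastula: no opening
  scene <- build_blastula(32, subdivisions = 1)
  expect_equal(opening_diameter(scene), 0)

  # synthetic hemispherical cup of small cells, rim on the equator at R
  R <- 4
  pl <- place_cells_on_sphere(128, R)
  keep <- which(pl$centers[, 3] < 0.1)
  cells <- lapply(seq_along(keep), function(j) {
    i <- keep[j]
    icosphere(0, radius = 0.35, center = pl$centers[i, ],
              apical_axis = pl$axes[i, ], type = "ectoderm", id = j)
  })
  cup <- mc_scene(cells)
  d <- opening_diameter(cup, oral_axis = c(0, 0, 1))
  expect_gt(d, 2 * R * 0.95)
  expect_lt(d, 2 * R * 1.05)

  # rotation + translation invariance of the metric (axis rotated along)
  th <- 0.7
  Rot <- rbind(c(1, 0, 0),
               c(0, cos(th), -sin(th)),
               c(0, sin(th), cos(th)))
  rotated <- cup
  for (i in seq_along(rotated$cells))
    rotated$cells[[i]]$positions <-
      sweep(rotated$cells[[i]]$positions %*% t(Rot), 2, c(5, 1, -2), "+")
  # invariant up to the azimuthal binning of the rim walk
  d2 <- opening_diameter(rotated, oral_axis = as.numeric(Rot %*% c(0, 0, 1)))
  expect_equal(d2, d, tolerance = 0.02)
})

test_that("run products: measurement stream, manifest and snapshots", {
  out <- file.path(tempdir(), "mc_run_products")
  unlink(out, recursive = TRUE)
  run <- run_script("
scene:
  builder: single_cell
  subdivisions: 1
end_time: 10
record_every: 2
output:
  snapshot_every: 4
  format: obj
", out_dir = out, seed = 2)
  expect_true(run$ok)

  m <- utils::read.csv(file.path(out, "measurements.csv"))
  # strictly increasing time, one record per cadence step
  expect_true(all(diff(unique(m$time)) > 0))
  expect_equal(nrow(m), length(unique(m$time)))

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 2)
  expect_equal(manifest$params$dt, 0.05)
  expect_equal(manifest$steps_per_time_unit, 20)

  snaps <- list.files(file.path(out, "snapshots"), pattern = "\\.obj$")
  expect_equal(length(snaps), 3)   # t = 2, 6, 10 under cadence 4
  expect_true(file.exists(file.path(out, "final_state.json")))

  # offline re-measurement of the snapshots
  mm <- measure_snapshots(file.path(out, "snapshots"))
  expect_equal(nrow(mm), 3)
  expect_true(all(abs(mm$volume / run$scene$cells[[1]]$V0 - 1) < 0.05))
  unlink(out, recursive = TRUE)
})

test_that("scene state survives a save/load round trip", {
  a <- icosphere(1, type = "endoderm")
  b <- icosphere(1, center = c(2, 0, 0), type = "ectoderm")
  a$adhesive[] <- TRUE; b$adhesive[] <- TRUE
  scene <- mc_scene(list(a, b))
  run <- run_simulation(scene, list(), end_time = 5, record_every = 1,
                        seed = 6)
  path <- tempfile(fileext = ".json")
  save_scene(run$scene, path)
  back <- load_scene(path)
  expect_equal(back$time, run$scene$time)
  expect_equal(back$cells[[1]]$positions, run$scene$cells[[1]]$positions,
               tolerance = 1e-12)
  expect_equal(back$cells[[2]]$l0, run$scene$cells[[2]]$l0,
               tolerance = 1e-12)
  expect_identical(back$cells[[1]]$type, "endoderm")
  expect_equal(nrow(back$bonds), nrow(run$scene$bonds))
  expect_equal(back$prev[[1]], run$scene$prev[[1]], tolerance = 1e-12)
  unlink(path)
})
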