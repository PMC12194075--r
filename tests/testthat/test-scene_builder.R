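test_that("spherical cell placement is uniform, centered and deterministic", {
  pl <- place_cells_on_sphere(256, radius = 5)
  expect_equal(sqrt(rowSums(pl$centers^2)), rep(5, 256), tolerance = 1e-12)
  # centroid near the origin
  expect_lt(sqrt(sum(colMeans(pl$centers)^2)), 0.05 * 5)
  # nearest-neighbour spacing coefficient of variation <= 0.15
  d <- as.matrix(dist(pl$centers)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lte(stats::sd(nn) / mean(nn), 0.15)
  # outward apical axes
  expect_equal(pl$axes, pl$centers / 5, tolerance = 1e-12)
  expect_identical(pl, place_cells_on_sphere(256, radius = 5))
})

test_that("cap plates select the expected area fraction, monotonically", {
  pl <- place_cells_on_sphere(256, radius = 5)
  # whole sphere
  expect_length(select_plate(pl$centers, plate_shape("cap", angle = pi)), 256)
  # quarter of the cells: cap angle 60 degrees covers area fraction 1/4
  sel <- select_plate(pl$centers, plate_shape("cap", angle = pi / 3))
  expect_gt(length(sel), 64 * 0.9)
  expect_lt(length(sel), 64 * 1.1)
  # monotone in the cap angle
  sizes <- vapply(c(0.4, 0.8, 1.2, 1.6),
                  function(a) length(select_plate(pl$centers,
                                                  plate_shape("cap", a))), 1L)
  expect_true(all(diff(sizes) > 0))
})

test_that("irregular plate masks are connected around the plate center", {
  pl <- place_cells_on_sphere(512, radius = 7)
  for (kind in c("rectangle", "triangle", "t_shape", "star")) {
    sel <- select_plate(pl$centers, plate_shape(kind, size = 1.2,
                                                width = 1.4, height = 0.7))
    expect_gt(length(sel), 3)
    rings <- ring_decomposition(pl$centers, sel)   # errors if disconnected
    expect_setequal(unlist(rings), sel)
  }
})

test_that("ring decomposition starts at the center and matches geometry", {
  scene <- build_detached_plate(37, subdivisions = 0)
  ctr <- scene_centers(scene, current = FALSE)
  rings <- ring_decomposition(ctr, seq_len(37))
  expect_length(rings[[1]], 1)                  # single center cell
  expect_setequal(unlist(rings), 1:37)          # partition
  expect_false(any(duplicated(unlist(rings))))
  expect_length(rings, 4)                       # hex radius 3 -> rings 0..3
  expect_equal(lengths(rings), c(1, 6, 12, 18))

  # ring index increases with radial distance from the plate center
  r_geom <- sqrt(rowSums(ctr[, 1:2]^2))
  ring_of <- integer(37)
  for (i in seq_along(rings)) ring_of[rings[[i]]] <- i - 1
  expect_gt(stats::cor(ring_of, r_geom, method = "spearman"), 0.9)

  # a disconnected plate is rejected
  expect_error(ring_decomposition(ctr, c(1, 37)), "not connected")
})

test_that("constriction schedules realise the three modes", {
  scene <- build_detached_plate(37, subdivisions = 0)
  rings <- ring_decomposition(scene_centers(scene, FALSE), 1:37)

  sim <- constriction_schedule(rings, "simultaneous", start = 50,
                               interval = 100)
  expect_true(all(vapply(sim, function(e) e$start, 1) == 50))

  cf <- constriction_schedule(rings, "center_first", start = 50,
                              interval = 100)
  expect_equal(vapply(cf, function(e) e$start, 1), c(50, 150, 250, 350))
  # ring 3 (fourth ring) starts at start + 3 * interval
  expect_equal(cf[[4]]$start, 50 + 3 * 100)

  ef <- constriction_schedule(rings, "edge_first", start = 50,
                              interval = 500)
  # outermost ring starts first
  expect_equal(ef[[length(ef)]]$start, 50)
  expect_equal(ef[[1]]$start, 50 + 3 * 500)
})

test_that("hexagonal discs have centered-hexagonal counts and trim deterministically", {
  expect_equal(nrow(hex_disc_centers(61, 2)), 61)   # r = 4 full disc
  expect_equal(nrow(hex_disc_centers(91, 2)), 91)   # r = 5 full disc
  expect_equal(nrow(hex_disc_centers(19, 2)), 19)

  # 83 = 91-cell disc minus 8 outermost cells, deterministic
  a <- hex_disc_centers(83, 2)
  b <- hex_disc_centers(83, 2)
  expect_equal(nrow(a), 83)
  expect_identical(a, b)

  plate <- build_detached_plate(83, subdivisions = 0)
  expect_length(plate$cells, 83)
  ctr <- scene_centers(plate, FALSE)
  # flat at t = 0: all centers in the z = 0 plane
  expect_equal(ctr[, 3], rep(0, 83))
  # neighbour spacing = 2 * radius * packing
  d <- as.matrix(dist(ctr)); diag(d) <- Inf
  expect_equal(min(d), 2 * 1 * 0.98, tolerance = 1e-9)
})

test_that("blastula construction types cells and sizes the adhesive bands", {
  scene <- build_blastula(32, subdivisions = 1)
  types <- vapply(scene$cells, function(c) c$type, "")
  endo <- attr(scene, "endoderm")
  expect_true(all(types[endo] == "endoderm"))
  expect_true(all(types[-endo] == "ectoderm"))
  expect_gt(length(endo), 0)
  expect_lt(length(endo), 32)

  # hollow blastocoel: hull volume far exceeds the summed cell volumes
  R <- sqrt(sum(scene$cells[[1]]$center^2)) + 1
  hull_vol <- 4 * pi * R^3 / 3
  cell_vol <- sum(vapply(scene$cells, function(c) c$V0, 1))
  expect_gt(hull_vol, 2 * cell_vol)

  # endoderm adhesive band 20-65% is smaller than ectoderm 20-100%
  n_adh <- vapply(scene$cells, function(c) sum(c$adhesive), 1L)
  expect_lt(mean(n_adh[endo]), mean(n_adh[-endo]))

  # every built cell passes mesh validation
  for (cell in scene$cells) expect_no_error(validate_mesh(cell))
})

test_that("blastula neighbours bond during equilibration", {
  scene <- build_blastula(16, subdivisions = 1)
  run <- run_simulation(scene, list(),
                        end_time = attr(scene, "equilibration"),
                        record_every = 10, seed = 12)
  expect_true(run$ok)
  adj <- cell_adjacency(scene_centers(scene, FALSE))
  b <- run$scene$bonds
  bonded_pairs <- unique(paste(pmin(b$cell_a, b$cell_b),
                               pmax(b$cell_a, b$cell_b)))
  adj_pairs <- outer(1:16, 1:16, function(i, j) i < j & adj[cbind(i, j)])
  want <- which(adj_pairs, arr.ind = TRUE)
  have <- paste(want[, 1], want[, 2]) %in% bonded_pairs
  # every adjacent neighbour pair holds at least one bond
  expect_true(all(have))
})

test_that("planar ring scenes stay confined between the plates", {
  scene <- build_planar_scene(16, n_endoderm = 4, subdivisions = 1,
                              gap = 1.8)
  expect_length(scene$cells, 16)
  expect_length(attr(scene, "endoderm"), 4)
  expect_length(scene$planes, 2)
  run <- run_simulation(scene, list(), end_time = 30, record_every = 5,
                        seed = 3)
  expect_true(run$ok)
  ctr <- scene_centers(run$scene)
  expect_true(all(abs(ctr[, 3]) < 1.8 / 2))
  # plates themselves never move (they are scene constants)
  expect_equal(run$scene$planes[[1]]$point[3], 0.9)
  expect_equal(run$scene$planes[[2]]$point[3], -0.9)
  expect_error(build_planar_scene(16, gap = 0), "gap")
})

test_that("purse-string setup spares the apical cap and stiffens it", {
  ev <- purse_string_events(1L, band = c(20, 40), f_c = 0.1, start = 10,
                            ramp = 20)
  types <- vapply(ev, function(e) e$type, "")
  expect_equal(types, c("constriction", "stiffness", "stiffness"))
  expect_equal(ev[[1]]$band, c(20, 40))
  expect_equal(ev[[2]]$value, 1.8)
  expect_equal(ev[[3]]$value, 1.4)
  expect_error(purse_string_events(1L, band = c(0, 40)), "apical pole")

  # cap edges keep their rest lengths under the purse-string event
  scene <- build_single_cell(1)
  run <- run_simulation(scene, ev[1], end_time = 40, record_every = 10)
  cell <- run$scene$cells[[1]]
  cap <- select_region(cell, c(0, 19.999))
  fet <- scene$params$f_et
  expect_equal(cell$l0[cap$edges], fet * cell$l_rest[cap$edges],
               tolerance = 1e-12)
})
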