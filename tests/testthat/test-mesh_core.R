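test_that("icosphere subdivision produces the expected closed meshes", {
  # level 0: the icosahedron itself
  c0 <- icosphere(0)
  expect_equal(nrow(c0$positions), 12)
  expect_equal(nrow(c0$faces), 20)
  expect_equal(nrow(c0$edges), 30)

  # recurrence V' = V + E, F' = 4F, E' = V' + F' - 2 gives 42/80/120 at
  # level 1 and the production 642/1280 mesh at level 3
  c1 <- icosphere(1)
  expect_equal(nrow(c1$positions), 42)
  expect_equal(nrow(c1$faces), 80)
  expect_equal(nrow(c1$edges), 120)

  c3 <- icosphere(3)
  expect_equal(nrow(c3$positions), 642)
  expect_equal(nrow(c3$faces), 1280)

  # Euler characteristic 2 and closedness at every level 0-4
  for (lvl in 0:4) {
    cl <- icosphere(lvl)
    expect_equal(nrow(cl$positions) - nrow(cl$edges) + nrow(cl$faces), 2)
    expect_no_error(validate_mesh(cl))
  }
})

test_that("icosphere construction is deterministic and respects arguments", {
  a <- icosphere(2, radius = 1.5, center = c(1, 2, 3))
  b <- icosphere(2, radius = 1.5, center = c(1, 2, 3))
  expect_identical(a$positions, b$positions)
  expect_identical(a$faces, b$faces)
  expect_equal(sqrt(rowSums(sweep(a$positions, 2, c(1, 2, 3), "-")^2)),
               rep(1.5, 162), tolerance = 1e-12)
  expect_error(icosphere(2, radius = Inf), "radius")
  expect_error(icosphere(2, center = c(0, NA, 0)), "center")
  expect_error(icosphere(-1), "subdivisions")
})

test_that("signed volume matches closed forms and scaling laws", {
  cube <- unit_cube_mesh()
  expect_equal(signed_volume(cube), 1.0, tolerance = 1e-14)

  # icosphere volume approaches the ball volume from below, within 1% at
  # level 3, monotonically in the level
  vols <- vapply(0:3, function(l) signed_volume(icosphere(l)), 1)
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 * pi / 3))
  expect_lt((4 * pi / 3 - vols[4]) / (4 * pi / 3), 0.01)

  # scaling: x2 coordinates -> x8 volume
  c2 <- icosphere(2)
  scaled <- c2
  scaled$positions <- 2 * c2$positions
  expect_equal(signed_volume(scaled), 8 * signed_volume(c2),
               tolerance = 1e-12)

  # origin independence
  moved <- c2
  moved$positions <- sweep(c2$positions, 2, c(10, -4, 7), "+")
  expect_equal(signed_volume(moved), signed_volume(c2), tolerance = 1e-9)

  # open mesh rejected
  open_mesh <- list(positions = cube$positions, faces = cube$faces[-1, ])
  expect_error(signed_volume(open_mesh), "not closed")
})

test_that("band coordinate maps the polar arc to 0-100%", {
  axis <- c(0, 0, 1)
  expect_equal(band_coordinate(c(0, 0, 1), c(0, 0, 0), axis), 0)
  expect_equal(band_coordinate(c(1, 0, 0), c(0, 0, 0), axis), 50)
  expect_equal(band_coordinate(c(0, 0, -1), c(0, 0, 0), axis), 100)
  # theta = 117 degrees -> 65%
  th <- 117 * pi / 180
  expect_equal(band_coordinate(c(sin(th), 0, cos(th)), c(0, 0, 0), axis),
               65, tolerance = 1e-9)
  expect_error(band_coordinate(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)),
               "apical_axis")
  expect_error(band_coordinate(c(0, 0, 0), c(0, 0, 0), axis), "center")
})

test_that("region selection partitions the cortex and matches a brute-force scan", {
  cell <- icosphere(3)
  all_sel <- select_region(cell, c(0, 100))
  expect_equal(length(all_sel$vertices), 642)
  expect_equal(length(all_sel$edges), nrow(cell$edges))

  # complementary bands cover all vertices, overlapping only at the boundary
  for (a in c(30, 50, 65)) {
    lo <- select_region(cell, c(0, a))
    hi <- select_region(cell, c(a, 100))
    expect_setequal(union(lo$vertices, hi$vertices), seq_len(642))
    ov <- intersect(lo$vertices, hi$vertices)
    expect_true(all(abs(cell$band[ov] - a) < 1e-12))
  }

  # brute-force polar-angle oracle for the 20-65% adhesive band
  d <- sweep(cell$positions, 2, cell$center, "-")
  theta <- acos(pmin(1, pmax(-1, (d %*% cell$apical_axis)[, 1] /
                               sqrt(rowSums(d^2)))))
  expected <- which(100 * theta / pi >= 20 & 100 * theta / pi <= 65)
  expect_setequal(select_region(cell, c(20, 65))$vertices, expected)

  # edges require both endpoints inside
  sel <- select_region(cell, c(20, 65))
  inset <- seq_len(642) %in% sel$vertices
  expect_true(all(inset[cell$edges[sel$edges, 1]] &
                  inset[cell$edges[sel$edges, 2]]))
  expect_error(select_region(cell, c(60, 20)), "band")
})

test_that("vertex normals are outward, radial on spheres, and translation invariant", {
  cell <- icosphere(2)
  n <- vertex_normals(cell)
  radial <- cell$positions / sqrt(rowSums(cell$positions^2))
  ang <- acos(pmin(1, rowSums(n * radial)))
  expect_lt(max(ang) * 180 / pi, 2)   # within 2 degrees of radial

  moved <- cell
  moved$positions <- sweep(cell$positions, 2, c(5, 5, 5), "+")
  expect_equal(vertex_normals(moved), n, tolerance = 1e-12)

  cube <- unit_cube_mesh()
  ncube <- vertex_normals(cube)
  expect_equal(abs(ncube), matrix(1 / sqrt(3), 8, 3), tolerance = 1e-12)
  # corner at the origin points along (-1,-1,-1)
  expect_equal(ncube[1, ], -c(1, 1, 1) / sqrt(3), tolerance = 1e-12)
})

test_that("mesh snapshots round trip through OBJ and VTK carries scalars", {
  scene <- mc_scene(list(icosphere(1, type = "endoderm"),
                         icosphere(1, center = c(3, 0, 0),
                                   type = "ectoderm")))
  tmp <- tempfile(fileext = ".obj")
  write_obj(scene, tmp)
  back <- read_obj(tmp)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$positions, scene$cells[[i]]$positions,
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_identical(back[[i]]$faces, scene$cells[[i]]$faces)
    expect_identical(back[[i]]$type, scene$cells[[i]]$type)
  }
  vtk <- tempfile(fileext = ".vtk")
  write_vtk(scene, vtk)
  lines <- readLines(vtk)
  expect_true(any(grepl("^POINTS 84 double", lines)))
  expect_true(any(grepl("^SCALARS band double", lines)))
  expect_true(any(grepl("^SCALARS cell_type int", lines)))
  unlink(c(tmp, vtk))
})
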