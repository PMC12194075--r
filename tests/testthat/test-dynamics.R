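test_that("verlet step reproduces discrete closed forms", {
  # c = 0, a = 0: uniform motion
  expect_equal(verlet_step(2, 1, 0, 0.1, 0), 3)

  # c = 0, constant a from rest: after N steps x = a dt^2 N (N + 1) / 2
  a <- 0.3; dt <- 0.05; N <- 200
  x <- 0; xp <- 0
  for (i in seq_len(N)) {
    xn <- verlet_step(x, xp, a, dt, 0)
    xp <- x; x <- xn
  }
  expect_equal(x, a * dt^2 * N * (N + 1) / 2, tolerance = 1e-12)

  # c = 1: velocity fully damped each step, x_{n+1} = x_n + a dt^2
  expect_equal(verlet_step(5, -100, 2, 0.1, 1), 5 + 2 * 0.01)

  expect_error(verlet_step(0, 0, 0, -1, 0.2), "dt")
  expect_error(verlet_step(0, 0, 0, 0.1, 2), "damping")
})

test_that("undamped verlet energy stays bounded over 1e4 steps", {
  # single scalar spring: F = -k x, m = 1
  k <- 1; dt <- 0.05
  x <- 1; xp <- 1  # start at rest at amplitude 1
  energy <- function(x, xp) {
    v <- (x - xp) / dt
    0.5 * v^2 + 0.5 * k * ((x + xp) / 2)^2
  }
  e0 <- NULL
  emax <- -Inf; emin <- Inf
  for (i in seq_len(10000)) {
    xn <- verlet_step(x, xp, -k * x, dt, 0)
    xp <- x; x <- xn
    e <- energy(x, xp)
    if (i == 100) e0 <- e
    if (i > 100) { emax <- max(emax, e); emin <- min(emin, e) }
  }
  # bounded oscillation, no secular growth
  expect_lt(emax / e0, 1.05)
  expect_gt(emin / e0, 0.95)
})

test_that("a perturbed free cell relaxes under damping", {
  scene <- build_single_cell(1)
  set.seed(5)
  scene$cells[[1]]$positions <- scene$cells[[1]]$positions +
    matrix(stats::rnorm(42 * 3, sd = 0.05), 42, 3)
  run <- run_simulation(scene, list(), end_time = 100, record_every = 5)
  expect_true(run$ok)
  kin <- run$kinetic
  expect_lt(kin[length(kin)], 1e-8)
  expect_lt(kin[length(kin)], kin[1])
})

test_that("force accumulation composes the per-module contributions", {
  scene <- build_single_cell(1)
  F <- scene_forces(scene)
  expect_equal(F$total,
               F$elastic + F$volume + F$adhesion + F$collision +
                 F$confinement, tolerance = 1e-12)
  # relaxed-ish free cell: no interaction terms at all
  expect_equal(max(abs(F$adhesion)), 0)
  expect_equal(max(abs(F$collision)), 0)
  expect_equal(max(abs(F$confinement)), 0)

  # two-cell contact scene: global force sum comes from intracellular terms
  # only (interaction terms cancel pairwise)
  a <- icosphere(1); b <- icosphere(1, center = c(1.9, 0, 0))
  a$adhesive[] <- TRUE; b$adhesive[] <- TRUE
  two <- mc_scene(list(a, b))
  run <- run_simulation(two, list(), end_time = 2, record_every = 1, seed = 2)
  F2 <- scene_forces(run$scene)
  expect_equal(colSums(F2$total),
               colSums(F2$elastic) + colSums(F2$volume),
               tolerance = 1e-9)
  expect_gt(max(abs(F2$adhesion)), 0)
})

test_that("schedule semantics: rest lengths change only after the event starts", {
  scene <- build_single_cell(1)
  ev <- list(constriction_event(1, f_c = 0.1, band = c(0, 50), start = 10,
                                ramp = 20))
  sel <- select_region(scene$cells[[1]], c(0, 50))
  fet <- scene$params$f_et

  r1 <- run_simulation(scene, ev, end_time = 5, record_every = 5)
  expect_equal(r1$scene$cells[[1]]$l0,
               fet * r1$scene$cells[[1]]$l_rest, tolerance = 1e-12)

  r2 <- run_simulation(r1$scene, ev, end_time = 40, record_every = 5)
  l0 <- r2$scene$cells[[1]]$l0
  lrest <- r2$scene$cells[[1]]$l_rest
  expect_equal(l0[sel$edges], 0.1 * fet * lrest[sel$edges],
               tolerance = 1e-12)
  other <- setdiff(seq_along(l0), sel$edges)
  expect_equal(l0[other], fet * lrest[other], tolerance = 1e-12)
})

test_that("runs are bit-identical under the same seed and config", {
  build <- function() {
    a <- icosphere(1); b <- icosphere(1, center = c(2.0, 0, 0))
    a$adhesive[] <- TRUE; b$adhesive[] <- TRUE
    mc_scene(list(a, b))
  }
  ra <- run_simulation(build(), list(), end_time = 15, record_every = 1,
                       seed = 31)
  rb <- run_simulation(build(), list(), end_time = 15, record_every = 1,
                       seed = 31)
  expect_identical(ra$snapshots, rb$snapshots)
  expect_identical(ra$volumes, rb$volumes)
  expect_identical(ra$bond_counts, rb$bond_counts)
  expect_identical(ra$measurements, rb$measurements)
})

test_that("halving the time step leaves the constricted shape unchanged", {
  shape_at <- function(dt) {
    scene <- build_single_cell(1, params = default_params(dt = dt))
    ev <- list(constriction_event(1, f_c = 0.1, band = c(0, 50), start = 5,
                                  ramp = 20))
    run <- run_simulation(scene, ev, end_time = 120, record_every = 20)
    cell_elongation(run$scene$cells[[1]])
  }
  expect_equal(shape_at(0.05), shape_at(0.025), tolerance = 0.01)
})

test_that("a run continued mid-way matches the uninterrupted run", {
  build <- function() {
    a <- icosphere(1); b <- icosphere(1, center = c(2.0, 0, 0))
    a$adhesive[] <- TRUE; b$adhesive[] <- TRUE
    mc_scene(list(a, b))
  }
  full <- run_simulation(build(), list(), end_time = 12, record_every = 2,
                         seed = 8)
  part1 <- run_simulation(build(), list(), end_time = 6, record_every = 2,
                          seed = 8)
  part2 <- run_simulation(part1$scene, list(), end_time = 12,
                          record_every = 2)  # RNG stream continues in-session
  last_full <- full$snapshots[[length(full$snapshots)]]
  last_part <- part2$snapshots[[length(part2$snapshots)]]
  expect_equal(last_part, last_full, tolerance = 1e-12)
})

test_that("snapshot restart through the state file reproduces the run", {
  # deterministic bond regime so the restart does not depend on RNG state
  p <- default_params(adhesion_chance = 100, break_chance = 0)
  build <- function() {
    a <- icosphere(1); b <- icosphere(1, center = c(2.0, 0, 0))
    a$adhesive[] <- TRUE; b$adhesive[] <- TRUE
    mc_scene(list(a, b), params = p)
  }
  full <- run_simulation(build(), list(), end_time = 12, record_every = 2,
                         seed = 4)
  part1 <- run_simulation(build(), list(), end_time = 6, record_every = 2,
                          seed = 4)
  path <- tempfile(fileext = ".json")
  save_scene(part1$scene, path)
  restored <- load_scene(path)
  expect_equal(restored$time, 6)
  part2 <- run_simulation(restored, list(), end_time = 12, record_every = 2,
                          seed = 4)
  expect_equal(part2$snapshots[[length(part2$snapshots)]],
               full$snapshots[[length(full$snapshots)]], tolerance = 1e-9)
  unlink(path)
})
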