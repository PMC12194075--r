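# morphocell

A 3D deformable-cell vertex model for studying how epithelial sheets bend
— in particular, how apical constriction, cell–cell adhesion and cortical
stiffness drive the invagination of an endodermal plate into a hollow
blastula (gastrulation in diploblastic embryos such as sea anemones and
stony corals). It is written for computational and developmental
biologists who want to run such experiments, change cell-level mechanics,
and measure the resulting cell and tissue shapes.

## The model

Each cell is a separate closed triangulated cortex (an icosphere; 642
vertices / 1280 faces at production resolution) of point masses connected
by nonlinear elastic edges:

- **Cortical elasticity** — edge force `F = -(k/l0) x² - k x` with
  `x = l - l0`: strain-stiffening, so stretching resists more than
  compression.
- **Cortical strain** — all rest lengths are factorised `l0 = f_et l_rest`,
  keeping the cortex taut against the conserved volume.
- **Constriction** — timed events set `l0 = f_c f_et l_rest` on a region
  (e.g. the apical band 0–50% of the polar arc), ramped linearly.
- **Volume conservation** — divergence-theorem cell volume
  `V = ⅓ Σ (x_i · n̂_i) A_i`; deviations from `V0` push every vertex along
  its outward normal with magnitude `k_v |V - V0| / V0`.
- **Adhesion** — stochastic bonds between adhesive-band vertices of
  neighbouring cells; constant pull `k_adh` with a linear ramp below
  `lin_length` (continuous at the junction).
- **Collision** — vertex-through-triangle contacts found via an AABB broad
  phase; restoring force `k_col × depth` on the intruding vertex and,
  with opposite sign, barycentrically on the three face corners.
- **Dynamics** — damped position Verlet,
  `x_{n+1} = (2-c) x_n - (1-c) x_{n-1} + a Δt²`.

Scene builders assemble single cells, detached hexagonal plates, planar
rings between confining plates, and blastulas of 32–1024 typed cells with
plate-shape masks (cap, rectangle, triangle, T, star), ring
decompositions and the three constriction modes (simultaneous,
center-first, edge-first).

## Worked example

Constrict the apical half of a single free cell and measure the result:

```r
library(morphocell)

scene  <- build_single_cell(subdivisions = 2)
events <- list(constriction_event(1, f_c = 0.1, band = c(0, 50),
                                  start = 10, ramp = 50))
run <- run_simulation(scene, events, end_time = 150, record_every = 10,
                      seed = 1)
run
#> <mc_run> completed, t = 150, 15 recorded step(s), 1 cell(s)
#>   max |V - V0| / V0 over run: 0.00287; final bonds: 0

round(subset(measure_scene(run$scene), TRUE,
             c(volume, volume_error, height, width, elongation,
               sphericity)), 4)
#>   volume volume_error height  width elongation sphericity
#> 1 4.0354      -0.0029  1.718 2.1856      0.786     0.9757
```

The cell's volume stayed within 0.3% of its rest volume throughout the
run while the apical cap collapsed: the cell flattened (height 1.72
against width 2.19, elongation 0.79 < 1) instead of elongating —
a detached cell cannot become columnar from apical constriction alone; it
needs neighbours to confine its lateral expansion. Building a plate and
constricting it (`build_detached_plate(19)` plus the same event on all
cells) makes the center cell's elongation rise above the detached value.

Whole experiments can also be declared in YAML scripts (see
`inst/experiments/`) and run from R (`run_script()`) or from the bundled
CLI:

```sh
inst/cli/morphocell run inst/experiments/blastula-256-simultaneous.yaml \
    --out results/blastula --seed 1
```

Outputs are a measurement CSV stream, OBJ/VTK mesh snapshots with a bond
table, a JSON run manifest, and a restartable state file.

## Layout

- `R/`, `src/` — package code and the compiled physics core
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/model-methods.Rmd` — the model, parameters and design
  choices, including everything treated as a calibration decision
- `inst/experiments/` — full-size experiment scripts with their expected
  qualitative outcomes
- `inst/cli/morphocell` — command-line entry point
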