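---
title: "The deformable-cell model: mechanics, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deformable-cell model: mechanics, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

morphocell simulates epithelial morphogenesis -- above all apical
constriction and the invagination of an endodermal plate into a hollow
blastula -- with fully three-dimensional, individually deformable cells.
This vignette is the package's own account of the model: the forces, the
integrator, the tunable parameters and their defaults, what the scene
builders emulate, and the design decisions taken where more than one
reasonable choice existed.

## The cell

A cell is a closed triangulated cortex: an icosphere whose vertices are
point masses and whose edges are nonlinear elastic elements. Subdivision
level 3 gives 642 vertices and 1280 faces per cell and is the production
resolution; level 2 (162 / 320) behaves the same qualitatively and is the
default for desk-scale experiments and the test suite, which keeps a full
suite run in minutes rather than hours. Positions are in model length
units; the default cell radius is 1.

Regions on the cortex are addressed by the *band coordinate*: the polar
angle of a vertex from the apical pole, as a percentage of the arc (0 =
apical pole, 50 = equator, 100 = basal pole). "Apical 0--50%" therefore
means the apical hemisphere. Percent-of-polar-angle was chosen over
percent-of-height or percent-of-area because it makes "0--50%" an exact
hemisphere, which is how the region notation is used throughout the
experiments. Band membership is assigned once, on the undeformed sphere,
and travels with the vertices afterwards: a constricting apical region
drags its adhesive band along rather than re-selecting vertices every
step. An edge belongs to a band only when *both* endpoints do, so a band
boundary never half-constricts an edge.

## Forces

**Cortical elasticity.** Each edge responds with
$F = -\frac{k}{l_0}x^2 - kx$, $x = l - l_0$: a spring whose stiffness
grows with extension, so stretching is harder than compression (cortical
strain stiffening), while compressed edges push back only weakly (excess
cortex folds away). The response has a second zero at $x = -l_0$; past
that point the analytic expression would become anti-restorative, so the
force is clamped to zero there -- a design choice of this package. In
practice edges essentially never reach that regime, because volume
conservation keeps the cortex stretched.

**Cortical strain.** All rest lengths are factorised at run time as
$l_0 = f_{et}\, l_{rest}$ with $0 < f_{et} \le 1$. Because the conserved
volume prevents the cortex from actually shrinking, every edge stays
stretched and the surface stays taut and smooth -- the discrete analogue
of a cell removing excess cortical material. With uniform $f_{et}$ and
uniform stiffness a free cell stays spherical; the default $f_{et} = 0.8$
keeps a moderate resting tension without pushing edges deep into the
stiffening regime.

**Constriction.** A constriction event multiplies the strained rest
length of a region's edges by the constriction factor $f_c$
($l_0 = f_c\, f_{et}\, l_{rest}$), ramped linearly from 1 to $f_c$ over
the event's ramp duration (default 50 time units -- "gradually", to avoid
shock loading; the exact ramp is a calibration choice). Constriction
composes multiplicatively with cortical strain so that releasing an event
would restore the strained baseline. When events overlap on an edge the
latest-started event wins. The constricted edges almost never reach their
tiny targets -- neighbouring elements and the conserved volume resist --
which is exactly the intended behaviour: the target sets a tension, not a
geometry.

**Volume conservation.** The cell volume is the divergence-theorem sum
$V = \frac{1}{3}\sum_i (\vec{x}_i \cdot \hat{n}_i) A_i$ over faces, and
deviations from the rest volume $V_0$ generate a restoring force of
magnitude $k_v |V - V_0| / V_0$ per vertex, outward when the cell is
under volume and inward when over. Two weightings of that magnitude are
implemented. The *uniform* variant applies the same magnitude to every
vertex; it is the literal reading of "force per vertex", but on a
deformed cell whose vertex density varies (e.g. a constricted apical cap)
the per-vertex normals no longer cancel and the cell propels itself --- a
persistent momentum leak that visibly translates constricting cells. The
default *area* weighting scales each vertex by its share of the surface
area vector, which makes the volume force of every closed cell sum to
exactly zero (a true pressure force) while keeping the same mean
magnitude. The uniform variant remains available as
`volume_weighting = "uniform"`.

**Adhesion.** Vertices inside a cell-type's adhesive band may bond a
vertex of another cell. Bonded pairs attract with a constant force
$k_{adh}$, except below the cutoff `lin_length` where the force ramps
linearly to zero -- a continuous junction that prevents bonded cells from
"bouncing" around zero separation. Bond turnover is stochastic and per
step: each existing bond breaks with `break_chance`%, then every unbonded
adhesive vertex bonds its nearest unbonded in-range partner (ties to the
lowest vertex index) with `adhesion_chance`%. A vertex holds at most one
bond. Turnover lets junctions migrate as cells deform; the break chance
matters mechanically, because a junction that releases too eagerly cannot
transmit the constriction pull to the neighbour (see *Defaults* below).

**Collision.** Interpenetration is detected vertex-against-triangle: a
vertex of one cell is in violation when its signed distance to the
nearest feature of another cell's boundary is negative. The response
pushes the intruding vertex along the violated face's outward normal with
force $k_{col} \times$ depth, and distributes the opposite force over the
face's three corners by the foot point's barycentric weights, so every
contact is momentum-free. Candidate pairs come from per-cell axis-aligned
bounding boxes inflated by at least the adhesion connect length (the same
broad phase serves bonding and collision), giving the linear-in-cells
scaling that makes blastula-size scenes tractable. Self-collision of a
cell with itself is not tested; the quasi-static regime and the taut
cortex keep cells star-shaped enough in all experiments here.

**Confinement.** Planar experiments hold the cells between two immovable
plates: any vertex crossing a plate receives stiffness x depth along the
plate normal.

## Dynamics

Newtonian dynamics with damped position Verlet:
$$\vec{x}_{n+1} = (2 - c)\vec{x}_n - (1 - c)\vec{x}_{n-1} +
  \vec{a}\,\Delta t^2 .$$
Per step: schedule events are applied, bounding boxes refreshed, bonds
updated, all forces accumulated, positions integrated, volumes and
lengths recomputed, and at the recording stride a snapshot taken. The
first step bootstraps with $\vec{x}_{-1} = \vec{x}_0$ (start at rest).
Figure-style times ("T = 85", "interval 100 units") are simulation-clock
times $t = \text{step} \times \Delta t$.

Defaults: $m = 1$ per vertex, $\Delta t = 0.05$, $c = 0.2$. These are
calibration choices (the model is used in its overdamped, quasi-static
regime, where only the final shapes matter): $\Delta t$ sits well below
the stability limit of the stiffest default force terms, and $c = 0.2$
relaxes transients in a few time units without freezing the dynamics.
Halving $\Delta t$ does not change steady-state constricted shapes beyond
tolerance (asserted in the test suite). Determinism is part of the
contract: bond draws go through R's RNG, so a seeded run is bit-identical
when repeated.

## Parameter defaults

| parameter | default | meaning / why |
|---|---|---|
| `dt` | 0.05 | integration step (time units) |
| `damping` | 0.2 | per-step viscous damping, overdamped regime |
| `mass` | 1 | vertex mass |
| `f_et` | 0.8 | cortical strain factor; resting tension |
| `k_v` | 50 | volume stiffness; holds volume errors ~0.1% even under strong constriction, an order below the stability limit |
| `k_adh` | 0.4 | bond pull in packed sheets; the planar-ring builder overrides to 1.2 (see below) |
| `lin_length` | 0.1 | bond linear-ramp cutoff |
| `connect_length` | 0.45 | bonding range; under half a cell radius so only facing surfaces bond |
| `adhesion_chance` | 60 | % per step per candidate vertex |
| `break_chance` | 0.2 | % per step per bond; the resulting mean bond life (~25 time units) lets junctions follow a constricting cap instead of slipping off it |
| `k_col` | 10 | collision restoring constant |
| `aabb_margin` | >= connect_length | broad-phase inflation |

The numeric values of $f_{et}$, $k_v$, $\Delta t$, $c$, $m$, $k_{adh}$,
$k_{col}$, the adhesion chances and the ramp durations are calibration
choices; they were calibrated here, once, against the model properties
that *are* part of the model's contract -- volume conservation within 1%,
a free cell that stays spherical, plate cells that elongate while a
detached constricting cell does not, and planar rings that invaginate --
and then frozen. All of them are exposed through `default_params()` and
the experiment script. Like the original experiments, which were
configured per scenario, the experiment types carry their own tables
where the geometry demands it: the planar ring builder defaults to
`k_adh = 1.2`, because a one-dimensional chain of cells holds far fewer
junctions per cell than a hexagonally packed sheet and needs a stronger
per-bond pull for the arc to fold inward, and to the three-zone stiffness
profile (stiff apical 0--30% k = 1, lateral 0.5, soft basal 0.1) under
which constricting cells wedge reliably -- with uniform stiffness the arc
sometimes stalls in a shallow symmetric pocket instead of folding
through.

**Numerical stability.** Constricted edges are roughly $1/f_c$ times
stiffer than relaxed ones (the $x^2/l_0$ term), and an explicit
integrator has a hard stability boundary: combining strong constriction
($f_c \le 0.1$) with a strong bond pull ($k_{adh} \gtrsim 0.6$ in packed
sheets) lets bonds drag cap edges deep into the stiffening regime and can
blow the integration up (a sudden kinetic-energy spike ending in a mesh
inversion, which aborts the run with the last good snapshot kept). The
default tables sit inside the stable regime for all desk-scale
experiments. For scenes that need stronger coupling, halve `dt` and
double `collision_stride`/`bond_stride`: the stiff elastic terms then
integrate at the finer step while the expensive interaction searches keep
their per-time-unit cost.

## Scenes

`build_blastula()` places $n$ cells (32--1024 in the experiments) on a
Fibonacci sphere lattice -- deterministic, works for any $n$, and keeps
the nearest-neighbour spacing within a few percent of uniform -- with the
blastula radius chosen so neighbouring cells just touch
($R = 0.98\,r\sqrt{\sqrt{3}\,n / 2\pi}$ from equating the per-cell sphere
area with a hexagonal packing cell). Apical poles point outward; the
interior stays hollow (the blastocoel). The endodermal plate is the cell
set whose centers fall in a shape mask around the oral pole: a polar cap,
or rectangle / triangle / T / star masks drawn in the azimuthal
equidistant chart. Endoderm cells default to the apico-lateral adhesive
band 20--65%, ectoderm to 20--100%.

`build_detached_plate()` builds hexagonally packed free-floating discs.
Full discs have centered-hexagonal counts $1 + 3r(r+1)$ (19, 37, 61, 91,
...); other counts -- such as the 83-cell plates of the constriction-mode
experiments -- are reached by removing outermost-ring cells at evenly
spaced angular positions, a deterministic and documented trimming rule.

`build_planar_scene()` is the cross-section experiment: a ring of 3D
cells between two plates at constant distance, apical axes pointing
radially outward, with a contiguous endodermal arc.

Ring constriction decomposes a plate into concentric rings by
breadth-first search from the center cell over the cell adjacency graph
(cells adjacent when their centers are closer than 1.3x the mean
nearest-neighbour distance -- robust to irregular plates, unlike raw
angular thresholds). The three modes start all rings together
(`simultaneous`), center outward (`center_first`), or edge inward
(`edge_first`), with a configurable inter-ring interval.

Scenes begin with an equilibration phase (50 time units by default)
during which neighbours bond before any event fires; schedules built by
the package start at $t = 50$ for this reason.

## Experiment design at desk scale

Two design choices in the packaged desk-scale experiments deserve
explanation. First, the paired plate comparisons (detached cell versus
plate, and constriction factor 0.1 versus 0.05 on a 19-cell plate) run in
the *deterministic junction regime* -- adhesion chance 100%, break chance
0 -- rather than with the stochastic defaults. The compared quantity is
the mechanical response to the constriction factor; on a 19-cell plate
the seed-to-seed variance of stochastic bond turnover is larger than that
effect, and a paired design removes exactly this nuisance variance (the
runs become reproducible independent of the seed). The stochastic regime
remains the default everywhere else, including the planar invagination
experiment, where junction turnover is mechanically necessary: junctions
must migrate apically with the constricting cap for the arc to fold, and
frozen junctions halve the invagination depth. Second, a detached plate
has no confining neighbours, so its "steady state" is a slow global
curling; the packaged comparisons therefore measure the late plateau of
the center-cell elongation (the window after the constriction response
has settled and before the plate closes on itself), stated explicitly in
the test protocols.

## Measurements

Cell *elongation* is the apico-basal extent over the maximal lateral
extent. *Apical extents* project the apical-band vertices on two tangent
directions of the plate frame. *Invagination depth* is the inward
displacement of the plate-center cell along the oral axis, measured in
the scene-centroid frame so rigid translations cancel. The *blastoporal
opening* is operationalised by an azimuthal rim walk: outer-layer
vertices are binned into sectors around the oral axis, each sector's rim
candidate is its furthest-along-axis vertex, and the opening is twice the
mean axis distance of the rim -- reported as 0 whenever the surface at
the axis is level with the rim (no fold yet). This rim rule is this
package's own operationalisation of a quantity usually judged visually
from embryo images.

## What the tests do and do not show

The test suite runs the desk-scale study conditions: level-2 cells,
plates of 19--37 cells, a 32-cell planar ring, and seeded stochastic
adhesion. They demonstrate the mechanisms -- volume conservation under
constriction, sphericity of free cells, elongation requiring neighbours,
constriction-factor monotonicity, the three constriction-mode shape
signatures, planar invagination -- on small systems. They do not assert
anything about full-size blastulas (256--1024 cells at level 3): those
runs take hours and their expected outcomes are qualitative (bowl-shaped
gastrulas, wide blastoporal openings). Scripts
for them ship under `inst/experiments/` with the expected qualitative
outcomes stated in comments, not asserted.

Known limitations: no remeshing or topology changes (no cell division),
no bending stiffness or viscoelastic cortex rheology, no self-collision
handling, no filopodial zippering; collisions assume the quasi-static
regime (a vertex crossing an entire cell between steps would be missed).
The uniform volume-force variant does not conserve momentum on deformed
cells -- kept only for comparison, as discussed above.
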