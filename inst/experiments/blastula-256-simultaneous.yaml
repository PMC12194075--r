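# Full-size invagination experiment: 256-cell blastula, cap plate,
# simultaneous apical constriction of the endoderm (f_c = 0.1).
# Expected qualitative outcome (not asserted in CI; a production-size run
# takes hours at subdivision level 3): the endodermal plate first bulges
# outward at its center while the plate edge moves in, then flattens and
# invaginates; the final gastrula is bowl-shaped with a wide blastoporal
# opening.
scene:
  builder: blastula
  n_cells: 256
  plate_shape: cap
  plate_angle: 1.0472     # ~ a quarter of the cells
  subdivisions: 3
params:
  f_et: 0.8
seed: 1
end_time: 600
record_every: 5
events:
  - type: constriction
    cells: endoderm
    band: [0, 50]
    value: 0.1
    start: 50
    ramp: 50
output:
  snapshot_every: 25
  format: obj
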