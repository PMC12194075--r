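# Planar cross-section experiment: 64 cells in a ring between two plates,
# 16-cell endodermal arc, apical constriction. Expected: the arc
# invaginates into the ring interior and the opening between the flanking
# ectoderm cells narrows.
scene:
  builder: planar_ring
  n_cells: 64
  n_endoderm: 16
  subdivisions: 2
  gap: 1.8
seed: 1
end_time: 800
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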