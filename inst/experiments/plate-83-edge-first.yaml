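# Detached 83-cell endodermal plate, edge-first ring constriction with a
# 100-time-unit interval. Expected: the plate curls up at the rim while
# the center stays convex for a long time, then closes into an oval shape.
scene:
  builder: detached_plate
  n_cells: 83
  subdivisions: 3
  adhesion_band: [20, 65]
seed: 1
end_time: 800
record_every: 5
events:
  - type: ring_constriction
    mode: edge_first
    f_c: 0.1
    interval: 100
    band: [0, 50]
    start: 50
output:
  snapshot_every: 25
  format: obj
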