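# Ring constriction starting at the plate center, interval 100 time units.
# Expected qualitative outcome: an early concave dip at the plate center
# that expands ring by ring ("dip in the center"), then invagination; end
# state similar to the simultaneous mode.
scene:
  builder: blastula
  n_cells: 256
  plate_shape: cap
  plate_angle: 1.0472
  subdivisions: 3
seed: 1
end_time: 800
record_every: 5
events:
  - type: ring_constriction
    mode: center_first
    f_c: 0.1
    interval: 100
    band: [0, 50]
    start: 50
output:
  snapshot_every: 25
  format: obj
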