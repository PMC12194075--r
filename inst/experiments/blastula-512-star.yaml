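# Star-shaped endodermal plate on a 512-cell blastula: irregular plates
# still invaginate; the star's folds help reduce the blastoporal opening
# but the gastrula stays bowl-like.
scene:
  builder: blastula
  n_cells: 512
  plate_shape: star
  plate_size: 1.1
  subdivisions: 3
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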