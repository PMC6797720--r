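# Two cell types seeded in the opposite inlets of a single-channel
# device. Coordinates are 1-based (row, col), origin top-left.
pixel_size_um: 20
mask:
  kind: single_channel
  well_radius_um: 400
  channel_width_um: 200
  channel_length_um: 2400
species:
  - name: green
    color: [0, 255, 0]
    death_prob: 0.3
    period: 1
  - name: blue
    color: [0, 0, 255]
    p_d: 0.3          # alias for death_prob
    period: 2
seeds:
  green: [[21, 21]]
  blue: [[21, 181]]
drug_events: []
total_steps: 60
steps_per_day: 4
rng_seed: 11
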