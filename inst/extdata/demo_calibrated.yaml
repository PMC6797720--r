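# Calibrated 11-day N2A vs MC3T3 run on the single-channel prototype,
# driven by the fitted per-interval iteration schedules at 4 steps per
# culture day. The schedules absorb net death (they were fitted with the
# death-free growth law), so death_prob is 0 here.
pixel_size_um: 20
mask:
  kind: single_channel
  well_radius_um: 400
  channel_width_um: 200
  channel_length_um: 2400
species:
  - name: N2A
    color: [0, 255, 0]
    death_prob: 0
    schedule:
      preset: N2A
  - name: MC3T3
    color: [75, 0, 130]
    death_prob: 0
    schedule:
      preset: MC3T3
seeds:
  N2A: [[21, 21]]
  MC3T3: [[21, 181]]
total_steps: 40
steps_per_day: 4
rng_seed: 53
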