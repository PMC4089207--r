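# Example phantom specification for read_phantom_spec(): a 128 x 128 scene
# with two flat bands, one bright ridge, one dark curve and two spots.
size: [128, 128]
background: [80, 160]
seed: 7
ridges:
  - points: [[30, 1], [26, 64], [34, 128]]
    amplitude: 70
    width: 2
  - points: [[90, 1], [100, 64], [88, 128]]
    amplitude: -60
    width: 2
spots:
  - center: [60, 30]
    amplitude: 80
    radius: 3
  - center: [64, 100]
    amplitude: -80
    radius: 3
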