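# Registry of the four public/announced radiograph landmark datasets this
# model family is trained on. Spacing values apply to the original image
# resolution; resize_sample() rescales them to the working size. The image
# files themselves are external drop-ins and are never required: the
# registry records geometry and split bookkeeping only.
domains:
  - id: 0
    name: head
    num_landmarks: 19          # lateral cephalogram reference points
    input_channels: 1
    target_size: [416, 512]
    spacing_mode: fixed_mm
    spacing_mm: [0.1, 0.1]     # at the original 1935x2400 resolution
    split: {train: 150, test: 250}
  - id: 1
    name: hand
    num_landmarks: 37
    input_channels: 1
    target_size: [352, 512]
    spacing_mode: wrist_width_mm
    reference_mm: 50           # assumed physical wrist width
    endpoints: [1, 5]          # wrist endpoints among the 37 landmarks
    split: {train: 595, test: 300}
  - id: 2
    name: chest
    num_landmarks: 6           # lung-field extrema, 3 per lung
    input_channels: 1
    target_size: [512, 512]
    spacing_mode: pixel
    split: {train: 204, test: 75}
  - id: 3
    name: pelvis
    num_landmarks: 10
    input_channels: 1
    target_size: [512, 512]
    spacing_mode: pixel
    split: {train: 100, test: 36}
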