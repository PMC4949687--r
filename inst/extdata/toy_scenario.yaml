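# Toy end-to-end scenario: 162-vertex icosphere, 3 subjects per chain.
seed: 7
smoothing_steps: 5
mesh:
  subdivisions: 2
  radius_mm: 50
phase:
  samples_per_run: 128
  tr: 2
  cycles_per_run: 8
  modality: visual
  delay_s: 2
  n_subjects: 3
  amplitude: 1.5
  noise_sd: 1
  patch:
    center_vertex: 1
    radius_mm: 45
reading:
  n_subjects: 3
  runs_per_subject: 2
  n_blocks: 32
  block_s: 16
  tr: 1
  noise_sd: 1
  effect: 0.6
  patch:
    center_vertex: 10
    radius_mm: 40
thresholds:
  vertex_p: 0.01
  alpha: 0.05
  iterations: 200
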