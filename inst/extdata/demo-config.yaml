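# Demo configuration for run_pipeline(): a small correlative scene that
# completes in well under a minute on one CPU.
seed: 7
synth:
  n_emitters: 24
  n_frames: 400
  ny: 72
  nx: 72
  sigma0: 150
  pixel_size: 107
  epsilon: 800
  tau_on: 2
  tau_off: 6
preproc:
  skip_frames: 20
sofi:
  order: 2
  flatten: true
postproc:
  deconv_iters: 8
sicm:
  shape_y: 72
  shape_x: 72
  pixel_size: 107
  radius: 50
  setpoint: 0.99
  hopping_height: 5000
  noise_sigma: 2
  n_microvilli: 12
coreg:
  n_sections: 8
  section_half_length: 1000
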