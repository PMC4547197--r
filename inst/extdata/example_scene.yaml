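# Example imaging run: a GFP-labeled synthetic neuron phantom sectioned by a
# 5 um light sheet. Note: YAML scientific notation needs the explicit sign
# (1.0e+12, not 1.0e12).
seed: 1
specimen:
  type: neurons
  n_cells: 6
  extent_um: 60
  voxel_size_um: 1
  seed: 7
fluorophores:
  - fixture: gfp
sheet:
  thickness_um: 5
  height_um: 70
  lambda_ex_nm: 487.5
  photons: 1.0e+12
  z_um: 0
  attenuate: false
camera:
  film_width_um: 60
  film_height_um: 60
  resolution: [128, 128]
  aperture_radius_um: 5
  focus_scale_um: 25
  samples_per_pixel: 8
marching:
  step_um: 0.5
  jitter: true
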