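# Small demonstration scenario: 50 molecules at a dye:bp ratio of 1:8
# with wide staining heterogeneity, reduced frame count and field of view
# for quick runs. Coarser bins and a shorter extrapolation window suit
# the small population.
n_molecules: 50
mean_dye_per_bp: 0.125
heterogeneity: 2.5
relaxation_rate: 0.0
duration: 0.0
seed: 11
bin_width: 0.08
min_per_bin: 2
n_bins: 6
sim:
  native_extension_um: 5.0
  fov_length_px: 96
  frames_per_molecule: 40
  condition_label: toy
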