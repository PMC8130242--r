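body_mass_kg: 73.0
body_height_cm: 176.0
bm_weight_share: 0.04
active_marrow_share: 0.333333333333
rbm_density_g_cm3: 1.03
total_muscle_mass_g: 28000.0
lymph_node_fraction: 0.05
skeleton_mass_g: 10500.0
bone_density_g_cm3: 1.3
total_bone_surface_cm2: 51600.0
bones:
- bone: ulna
  fresh_weight_percent: 1.4
  surface_to_volume_cm2_cm3: 6.0
  irradiated_length_fraction: 0.304
- bone: radius
  fresh_weight_percent: 1.1
  surface_to_volume_cm2_cm3: 6.0
  irradiated_length_fraction: 0.378
- bone: humerus
  fresh_weight_percent: 3.7
  surface_to_volume_cm2_cm3: 4.5
  irradiated_length_fraction: 0.357
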