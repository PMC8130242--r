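components:
- component: dosimeter_position
  relative_1sd_pct: 10.0
  applies_to: per_dosimeter
- component: phantom_position
  relative_1sd_pct: 10.0
  applies_to: per_dosimeter
- component: fraction_irradiated
  relative_1sd_pct: 25.0
  applies_to: per_substructure
- component: source_variation
  relative_1sd_pct: 5.0
  applies_to: global
- component: cable_irradiation
  relative_1sd_pct: 1.0
  applies_to: global
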