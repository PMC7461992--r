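# First three 20-min oxygen periods of U.S. Navy Treatment Table 6 at
# 2.8 bar, separated by 5-min air breaks; risk evaluated at the end of the
# third oxygen period.
condition: DRY_REST
segments:
- po2_bar: 2.8
  duration_min: 20.0
  kind: oxygen
- po2_bar: 0.6
  duration_min: 5.0
  kind: air
- po2_bar: 2.8
  duration_min: 20.0
  kind: oxygen
- po2_bar: 0.6
  duration_min: 5.0
  kind: air
- po2_bar: 2.8
  duration_min: 20.0
  kind: oxygen
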