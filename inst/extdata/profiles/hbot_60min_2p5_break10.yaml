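# One-hour hyperbaric oxygen treatment at 2.5 bar with a 10-min air break:
# two 30-min oxygen periods (the break is not counted in the treatment hour).
condition: DRY_REST
segments:
- po2_bar: 2.5
  duration_min: 30.0
  kind: oxygen
- po2_bar: 0.5
  duration_min: 10.0
  kind: air
- po2_bar: 2.5
  duration_min: 30.0
  kind: oxygen
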