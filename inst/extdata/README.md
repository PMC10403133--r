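Published summary tables of the 2012-2021 southern Port Phillip Bay
bottlenose dolphin photo-identification programme, stored as plain CSV:

- `portphillip_yearly_images.csv` - per-season collection date range and
  number of fin images.
- `portphillip_grading_summary.csv` - image counts per quality band and,
  for usable bands, the number of identified fins.
- `portphillip_distinctiveness.csv` - identified adult individuals per fin
  distinctiveness class.
- `portphillip_occasions.csv` - secondary months per season-year entering
  the robust-design models, with the published closure-test P values.
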