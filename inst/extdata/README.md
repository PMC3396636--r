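# Example datasets

All files here are **synthetic**: they are deterministic output of
`rechase::fixture_tables()` (noiseless simulator scenarios) and can be
regenerated with, e.g., `fixture_tables("are_like", dir)`.

- `fig1a_*`: conventional chase of an infinitely stable mRNA in cells
  doubling every 6 h, 0-24 h. The uncorrected globin:actin ratio shows the
  6-h apparent-decay artifact.
- `are_like_*`: reverse chase of a short-lived AU-rich-element reporter,
  5-min spacing over 100 min; observed decay constant 0.0338 per min at
  j = 0.0004 per min.

Each `_truth.json` sidecar records every generative parameter.
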