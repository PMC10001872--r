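# Bundled national assessment: synthetic concentrations matching the
# published seven-province rice survey summaries, national concentration
# model shared across groups, intake/body-weight values are documented
# package assumptions (see the methods vignette).
data:
  summary: nepal_table1
  synthesize: true
  truncate: false
tox: default
groups:
  - {name: national, ir: 0.32, bw: 60}
  - {name: women, ir: 0.36, bw: 52}
  - {name: children, ir: 0.26, bw: 27}
  - {name: preschoolers, ir: 0.21, bw: 16}
  - {name: toddlers, ir: 0.13, bw: 11}
iterations: 10000
seed: 42
mode: fitted
levels: [0.5, 0.75, 0.9, 0.95, 0.975, 0.99, 0.999]
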