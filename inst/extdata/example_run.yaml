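# Example riboQueue pipeline configuration (see readPipelineConfig()).
seed: 42
stages: [simulate, process, metagene, queue, enrich, readthrough]
sim:
  nOrfs: 300
conditions:
  wt:
    replicates: 2
    queueAmplitude: 0
  new1d:
    replicates: 2
queue:
  minCoverage: 1    # synthetic libraries: 1e6 RPM shared by 300 ORFs
enrich:
  windowCodons: 7
  alpha: 0.05
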