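macrophage_lineage:
  diameter_px: 142.0
  sigma_px: 71.0
neutrophil:
  diameter_px: 104.0
  sigma_px: 52.0
eosinophil:
  diameter_px: 126.0
  sigma_px: 63.0
lymphocyte:
  diameter_px: 61.0
  sigma_px: 30.5
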