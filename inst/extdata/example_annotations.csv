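tile_id,x,y,cell_class,assessor_id
demo_t001,50.0142409319857,42.991930961981,lymphocyte,assessor1
demo_t001,38.8060687257745,43.4805877607647,neutrophil,assessor1
demo_t001,16.4143833048622,33.4683497811778,neutrophil,assessor1
demo_t001,31.1869535515657,38.3854897262814,lymphocyte,assessor1
demo_t001,57.0216564182639,7.96341501219741,neutrophil,assessor1
demo_t001,28.7178298923206,53.4230055958802,neutrophil,assessor1
demo_t001,51.6906931050491,40.594581379681,lymphocyte,assessor2
demo_t001,42.2210258186712,41.4705295216146,neutrophil,assessor2
demo_t001,15.7533088978151,28.9791261738137,neutrophil,assessor2
demo_t001,31.9741198375128,33.6570353034442,lymphocyte,assessor2
demo_t001,57.4733784139483,8.55545003161601,neutrophil,assessor2
demo_t001,29.6172632965073,50.7448843123193,neutrophil,assessor2
demo_t001,51.1051727160227,39.1046738813445,lymphocyte,assessor3
demo_t001,42.0899045392147,44.9708847866556,neutrophil,assessor3
demo_t001,16.7863276046761,30.2800071471155,neutrophil,assessor3
demo_t001,29.6365954138368,35.1141000207399,lymphocyte,assessor3
demo_t001,55.2297602481806,8.87399219526979,neutrophil,assessor3
demo_t001,27.9023248057234,50.1847914728155,neutrophil,assessor3
demo_t001,51.1100557839121,40.7641748299065,lymphocyte,assessor4
demo_t001,40.5110659134697,43.4235621291068,neutrophil,assessor4
demo_t001,16.4854417782621,31.0570967899383,neutrophil,assessor4
demo_t001,30.1793017519208,36.1170431292828,lymphocyte,assessor4
demo_t001,57.4358221744887,9.20759471415804,neutrophil,assessor4
demo_t001,29.3043547299618,52.4699302496867,neutrophil,assessor4
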