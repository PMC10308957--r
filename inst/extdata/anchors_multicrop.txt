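58,64
120,90
100,151
200,134
155,220
300,201
209,318
227,475
399,347
572,259
398,582
597,440
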