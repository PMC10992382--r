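enzyme,kcat_c,kcat_sd,km_c,km_sd
7002,12.3,0.7,194.6,35.7
RPE,16.4,0.7,172.4,23.6
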