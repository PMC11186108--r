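energy_kev,response
30,1.36
60,1.40
111,1.27
200,1.12
400,1.03
662,1.00
1250,0.99
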