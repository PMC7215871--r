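domain,NTD,MLD,CTD,TMD,Linker,CytLoops
NTD,1.000,0.912,0.905,0.801,0.653,0.623
MLD,0.912,1.000,0.805,0.810,0.614,0.531
CTD,0.905,0.805,1.000,0.853,0.654,0.557
TMD,0.801,0.810,0.853,1.000,0.564,0.454
Linker,0.653,0.614,0.654,0.564,1.000,0.514
CytLoops,0.623,0.531,0.557,0.454,0.514,1.000
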