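domain,NTD,MLD,CTD,TMD,Linker,CytLoops
NTD,1.000,0.901,0.935,0.906,0.643,0.742
MLD,0.901,1.000,0.797,0.897,0.610,0.592
CTD,0.935,0.797,1.000,0.890,0.628,0.766
TMD,0.906,0.897,0.890,1.000,0.628,0.633
Linker,0.643,0.610,0.628,0.628,1.000,0.470
CytLoops,0.742,0.592,0.766,0.633,0.470,1.000
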