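# Six-domain NPC1 partition used for the inter-domain correlation tables.
# Residue ranges are 1-based and inclusive; CytLoops deliberately lies
# inside the first TMD range (overlap between domains is permitted).
domains:
  NTD: ["30-250"]
  MLD: ["374-620"]
  CTD: ["861-1083"]
  TMD: ["260-373", "621-797", "1084-1278"]
  Linker: ["251-259"]
  CytLoops: ["290-337"]
atom_filter: backbone
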