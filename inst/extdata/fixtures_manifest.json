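{
  "species_tree.nwk": "dbb32f9f11709eb78ef0d69a894595cb",
  "subclade_tree.nwk": "808e1623526fe55bb8077311f99fdd3d",
  "characters.tsv": "a6b38d9a2c5c5de545065020511aea67",
  "provenance.tsv": "330f8a2d47830a268a269fa1b62eb556",
  "taxa_meta.tsv": "c107a3dc56ef115442b84c4c5bf1d438",
  "curdsi_sites.tsv": "144c2362f502f442df7023fe07c936e0",
  "table1.json": "d8b501b8995da0bbbb32ce6ae038f0de"
}
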