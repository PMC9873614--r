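{
  "taxonomies": [
    {
      "taxonomy_id": "TXFIG4",
      "species": "NCBITaxon:10090",
      "brain_region": "UBERON:0001384",
      "is_anchor": true,
      "dendrogram": "dendrogram.json",
      "nomenclature": "nomenclature.tsv",
      "curation": "curation.tsv"
    }
  ],
  "imports_stub": "imports_stub.tsv"
}
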