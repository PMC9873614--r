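{
  "taxonomy_id": "TXFIG4",
  "species": "NCBITaxon:10090",
  "brain_region": "UBERON:0001384",
  "is_anchor": true,
  "nodes": [
    {
      "accession": "CS100",
      "height": 1.0,
      "children": [
        {
          "accession": "CS101",
          "height": 0.4
        },
        {
          "accession": "CS102",
          "height": 0.5
        }
      ]
    }
  ]
}
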