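{
  "taxonomy_id": "TXFIG3",
  "species": "NCBITaxon:10090",
  "brain_region": "UBERON:0001384",
  "is_anchor": true,
  "nodes": [
    {
      "accession": "CS001",
      "height": 1.0,
      "children": [
        {
          "accession": "CS002",
          "height": 0.6,
          "children": [
            {
              "accession": "CS003",
              "height": 0.3
            }
          ]
        }
      ]
    }
  ]
}
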