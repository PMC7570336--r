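{
  "coordinate_name": "rbcLa-panel-v1",
  "positions": [66, 180, 263, 300, 372, 378, 492],
  "consensus": {
    "66": "C", "180": "C", "263": "A", "300": "A",
    "372": "A", "378": "A", "492": "A"
  },
  "core_types": [
    {
      "label": "1",
      "priority": 1,
      "required_states": {"300": "G", "372": "C"}
    },
    {
      "label": "2",
      "priority": 2,
      "required_states": {"378": "G", "492": "T"}
    },
    {
      "label": "1-2",
      "priority": 3,
      "required_states": {"180": "C", "300": "A", "372": "A", "378": "A", "492": "A"}
    }
  ],
  "marker_snps": [
    {"position": 66, "state": "T", "label": "target-marker-66"},
    {"position": 263, "state": "T", "label": "target-marker-263"}
  ],
  "core_positions": [180, 300, 372, 378, 492],
  "reference": "GTCCTGTACGATCAGGTACTCTTAACGCCTTACATTACGATTTAAACGTAATAAGTGTATTCACTCATCAATCACGCCGACTCGGGGTACCAACAACCTAGCGAGCCAGAATGTTACTGGATTAATAACCGTACGTTGGATACTACAGCCTTGCTTATTCCACAAGCCGCAGATCACGCCTCCAAAAATGAGCATATCTTCTTCTTAAGTAAAAGGTCGGCAAACGTTGTAAGTATGTTTAGTGGGTACTTTCTGGCTCCCTAACGTTGGGTCCACGCCCTACGACTTTCATATTCCCGAAGGTCCCTGCGGCCTTCTACAATTGGGGTCTCAGCAGTAAGCCTGTCTAGGCGAATAACTGGGTCCCGAGCAAGTGTAGTAATGCGTTATGGCTCCCTAAATATCGGAGACACGCCCTTTATTCGGAGTGTCTTTGGTGTTTAAAGAACGTGATGAGTTATGCCACCATTCAGTATCGAATCAGCTCGCAAAATTGTTATGGGGCCATTAAGCTCGCTGA"
}
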