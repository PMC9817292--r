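{
  "schema_version": "1.0",
  "records": [
    {
      "smiles": "CC(=O)Oc1ccccc1C(=O)O",
      "id": "fix001-crippen",
      "scores": [0.5131, -0.2783, -0.1526, -0.4195, 0.5437, 0.2811, 0.2811, 0.2811, 0.2811, 0.136, -0.2783, 0.1129, 0.00869999999999999],
      "attributes": {
        "method": "crippen",
        "logP": "1.3101"
      }
    },
    {
      "smiles": "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
      "id": "fix002-crippen",
      "scores": [0.5131, 0.123, 0.5131, 0.1944, 0.136, 0.2811, 0.2811, 0.136, 0.2811, 0.2811, 0.2423, 0.5131, -0.2783, -0.1526, 0.00869999999999999],
      "attributes": {
        "method": "crippen",
        "logP": "3.0732"
      }
    },
    {
      "smiles": "CC(=O)Oc1ccccc1C(=O)O",
      "id": "fix001-random",
      "scores": [-0.205126593141671, -1.40684191765399, -0.323435836110565, -0.751762696400818, -1.18935374326788, -0.279732266101227, -0.263219255492631, -0.0915366855405179, 0.443796593652432, -0.0316996870002613, -1.01020584855269, -0.621581529521124, -1.00110382376892, 1.30746186790618, -0.476783382323146, -1.46301623359098, 0.538017511228097, -2.59131828541072, -1.18630529013832, -1.09403643228326, 0.719456910787162],
      "attributes": {
        "method": "random",
        "logP": "1.3101"
      }
    }
  ]
}
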