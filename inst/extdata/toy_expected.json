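{
  "ontology": "TOY",
  "term_count": 7,
  "edge_count": 5,
  "obsolete": ["TOY:0000007"],
  "roots": ["TOY:0000001"],
  "labels": {
    "TOY:0000001": "anatomical entity",
    "TOY:0000002": "cell",
    "TOY:0000003": "neuron",
    "TOY:0000004": "glial cell",
    "TOY:0000005": "organelle",
    "TOY:0000006": "mitochondrion",
    "TOY:0000007": "obsolete membrane"
  },
  "parents": {
    "TOY:0000001": [],
    "TOY:0000002": ["TOY:0000001"],
    "TOY:0000003": ["TOY:0000002"],
    "TOY:0000004": ["TOY:0000002"],
    "TOY:0000005": ["TOY:0000001"],
    "TOY:0000006": ["TOY:0000005"],
    "TOY:0000007": []
  },
  "children": {
    "TOY:0000001": ["TOY:0000002", "TOY:0000005"],
    "TOY:0000002": ["TOY:0000003", "TOY:0000004"],
    "TOY:0000003": [],
    "TOY:0000004": [],
    "TOY:0000005": ["TOY:0000006"],
    "TOY:0000006": [],
    "TOY:0000007": []
  },
  "ancestors": {
    "TOY:0000001": [],
    "TOY:0000002": ["TOY:0000001"],
    "TOY:0000003": ["TOY:0000001", "TOY:0000002"],
    "TOY:0000004": ["TOY:0000001", "TOY:0000002"],
    "TOY:0000005": ["TOY:0000001"],
    "TOY:0000006": ["TOY:0000001", "TOY:0000005"],
    "TOY:0000007": []
  },
  "descendants": {
    "TOY:0000001": ["TOY:0000002", "TOY:0000003", "TOY:0000004", "TOY:0000005", "TOY:0000006"],
    "TOY:0000002": ["TOY:0000003", "TOY:0000004"],
    "TOY:0000003": [],
    "TOY:0000004": [],
    "TOY:0000005": ["TOY:0000006"],
    "TOY:0000006": [],
    "TOY:0000007": []
  },
  "path": {
    "TOY:0000001": ["TOY:0000001"],
    "TOY:0000002": ["TOY:0000001", "TOY:0000002"],
    "TOY:0000003": ["TOY:0000001", "TOY:0000002", "TOY:0000003"],
    "TOY:0000004": ["TOY:0000001", "TOY:0000002", "TOY:0000004"],
    "TOY:0000005": ["TOY:0000001", "TOY:0000005"],
    "TOY:0000006": ["TOY:0000001", "TOY:0000005", "TOY:0000006"],
    "TOY:0000007": ["TOY:0000007"]
  },
  "synonyms": {
    "TOY:0000001": [],
    "TOY:0000002": ["cellule"],
    "TOY:0000003": [],
    "TOY:0000004": ["neuroglia"],
    "TOY:0000005": [],
    "TOY:0000006": [],
    "TOY:0000007": []
  },
  "definitions": {
    "TOY:0000001": [],
    "TOY:0000002": [],
    "TOY:0000003": ["An electrically excitable cell."],
    "TOY:0000004": [],
    "TOY:0000005": [],
    "TOY:0000006": [],
    "TOY:0000007": []
  },
  "xrefs": {
    "TOY:0000006": ["GO:0005739"]
  },
  "searches": [
    {"query": "cell", "exact": false, "properties": false, "obsolete": false,
     "expect": ["TOY:0000002", "TOY:0000004"]},
    {"query": "cell", "exact": true, "properties": false, "obsolete": false,
     "expect": ["TOY:0000002"]},
    {"query": "cell", "exact": false, "properties": true, "obsolete": false,
     "expect": ["TOY:0000002", "TOY:0000003", "TOY:0000004"]},
    {"query": "CELL", "exact": true, "properties": false, "obsolete": false,
     "expect": ["TOY:0000002"]},
    {"query": "organelle", "exact": true, "properties": false, "obsolete": false,
     "expect": ["TOY:0000005"]},
    {"query": "cellule", "exact": true, "properties": true, "obsolete": false,
     "expect": ["TOY:0000002"]},
    {"query": "membrane", "exact": false, "properties": false, "obsolete": false,
     "expect": []},
    {"query": "membrane", "exact": false, "properties": false, "obsolete": true,
     "expect": ["TOY:0000007"]},
    {"query": "neuroglia", "exact": false, "properties": true, "obsolete": false,
     "expect": ["TOY:0000004"]},
    {"query": "zebra", "exact": false, "properties": true, "obsolete": true,
     "expect": []}
  ]
}
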