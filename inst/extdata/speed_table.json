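[
  {
    "class": "tree_broadleaved",
    "kind": "landcover",
    "speed": 5,
    "mode": "WALKING"
  },
  {
    "class": "tree_needleleaved",
    "kind": "landcover",
    "speed": 5,
    "mode": "WALKING"
  },
  {
    "class": "tree_other",
    "kind": "landcover",
    "speed": 2,
    "mode": "WALKING"
  },
  {
    "class": "shrub",
    "kind": "landcover",
    "speed": 5,
    "mode": "WALKING"
  },
  {
    "class": "herbaceous",
    "kind": "landcover",
    "speed": 3,
    "mode": "WALKING"
  },
  {
    "class": "sparse_herbaceous",
    "kind": "landcover",
    "speed": 4,
    "mode": "WALKING"
  },
  {
    "class": "cultivated",
    "kind": "landcover",
    "speed": 5,
    "mode": "WALKING"
  },
  {
    "class": "bare_desert",
    "kind": "landcover",
    "speed": 2,
    "mode": "WALKING"
  },
  {
    "class": "water",
    "kind": "landcover",
    "speed": 0,
    "mode": "NONE"
  },
  {
    "class": "primary",
    "kind": "road",
    "speed": 80,
    "mode": "MOTORIZED"
  },
  {
    "class": "secondary",
    "kind": "road",
    "speed": 60,
    "mode": "MOTORIZED"
  },
  {
    "class": "tertiary",
    "kind": "road",
    "speed": 10,
    "mode": "CYCLING"
  },
  {
    "class": "river",
    "kind": "river",
    "speed": 0,
    "mode": "NONE"
  }
]
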