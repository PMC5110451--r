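{
  "format": "nanoband-network",
  "version": 1,
  "variables": [
    {
      "name": "coating",
      "kind": "categorical",
      "states": [
        "uncoated",
        "coated"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "ph",
      "kind": "categorical",
      "states": [
        "acidic",
        "neutral",
        "basic"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "contamination",
      "kind": "categorical",
      "states": [
        "low",
        "high"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "morphology",
      "kind": "categorical",
      "states": [
        "spherical",
        "fibrous"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "aggregation",
      "kind": "categorical",
      "states": [
        "low",
        "medium",
        "high"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "particle_size",
      "kind": "categorical",
      "states": [
        "small",
        "medium",
        "large"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "surface_area",
      "kind": "categorical",
      "states": [
        "low",
        "high"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "surface_charge",
      "kind": "categorical",
      "states": [
        "negative",
        "neutral",
        "positive"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "reactivity",
      "kind": "categorical",
      "states": [
        "low",
        "high"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "solubility",
      "kind": "categorical",
      "states": [
        "insoluble",
        "partial",
        "soluble"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "dispersibility",
      "kind": "categorical",
      "states": [
        "low",
        "high"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "cmr",
      "kind": "categorical",
      "states": [
        "no",
        "yes"
      ],
      "tag": "physicochemical"
    },
    {
      "name": "concentration",
      "kind": "discretized-continuous",
      "states": [
        "[0,3.922)",
        "[3.922,11.76)",
        "[11.76,27.45)",
        "[27.45,58.82)",
        "[58.82,121.6)",
        "[121.6,247.1)",
        "[247.1,498)",
        "[498,1000]"
      ],
      "tag": "exposure",
      "bin_edges": [0, 3.92156862745098, 11.7647058823529, 27.4509803921569, 58.8235294117647, 121.56862745098, 247.058823529412, 498.039215686274, 1000]
    },
    {
      "name": "oel",
      "kind": "discretized-continuous",
      "states": [
        "[0.5,2)",
        "[2,8)",
        "[8,32)",
        "[32,128]"
      ],
      "tag": "dose-response",
      "bin_edges": [0.5, 2, 8, 32, 128]
    }
  ],
  "edges": [
    {
      "parent": "coating",
      "child": "aggregation"
    },
    {
      "parent": "ph",
      "child": "aggregation"
    },
    {
      "parent": "aggregation",
      "child": "particle_size"
    },
    {
      "parent": "particle_size",
      "child": "surface_area"
    },
    {
      "parent": "coating",
      "child": "surface_charge"
    },
    {
      "parent": "ph",
      "child": "surface_charge"
    },
    {
      "parent": "surface_area",
      "child": "reactivity"
    },
    {
      "parent": "contamination",
      "child": "reactivity"
    },
    {
      "parent": "coating",
      "child": "solubility"
    },
    {
      "parent": "ph",
      "child": "solubility"
    },
    {
      "parent": "coating",
      "child": "dispersibility"
    },
    {
      "parent": "surface_charge",
      "child": "dispersibility"
    },
    {
      "parent": "morphology",
      "child": "cmr"
    },
    {
      "parent": "reactivity",
      "child": "cmr"
    },
    {
      "parent": "dispersibility",
      "child": "concentration"
    },
    {
      "parent": "solubility",
      "child": "concentration"
    },
    {
      "parent": "cmr",
      "child": "oel"
    }
  ],
  "cpts": [
    {
      "child": "coating",
      "parents": [],
      "prob": [
        [0.5, 0.5]
      ]
    },
    {
      "child": "ph",
      "parents": [],
      "prob": [
        [0.333333333333333, 0.333333333333333, 0.333333333333333]
      ]
    },
    {
      "child": "contamination",
      "parents": [],
      "prob": [
        [0.5, 0.5]
      ]
    },
    {
      "child": "morphology",
      "parents": [],
      "prob": [
        [0.05, 0.95]
      ]
    },
    {
      "child": "aggregation",
      "parents": [
        "coating",
        "ph"
      ],
      "prob": [
        [0.1, 0.3, 0.6],
        [0.45, 0.35, 0.2],
        [0.2, 0.3, 0.5],
        [0.5, 0.3, 0.2],
        [0.15, 0.3, 0.55],
        [0.45, 0.35, 0.2]
      ]
    },
    {
      "child": "particle_size",
      "parents": [
        "aggregation"
      ],
      "prob": [
        [0.7, 0.2, 0.1],
        [0.2, 0.6, 0.2],
        [0.1, 0.2, 0.7]
      ]
    },
    {
      "child": "surface_area",
      "parents": [
        "particle_size"
      ],
      "prob": [
        [0.1, 0.9],
        [0.5, 0.5],
        [0.85, 0.15]
      ]
    },
    {
      "child": "surface_charge",
      "parents": [
        "coating",
        "ph"
      ],
      "prob": [
        [0.1, 0.2, 0.7],
        [0.15, 0.5, 0.35],
        [0.3, 0.4, 0.3],
        [0.2, 0.6, 0.2],
        [0.7, 0.2, 0.1],
        [0.35, 0.5, 0.15]
      ]
    },
    {
      "child": "reactivity",
      "parents": [
        "surface_area",
        "contamination"
      ],
      "prob": [
        [0.85, 0.15],
        [0.5, 0.5],
        [0.6, 0.4],
        [0.25, 0.75]
      ]
    },
    {
      "child": "solubility",
      "parents": [
        "coating",
        "ph"
      ],
      "prob": [
        [0.55, 0.3, 0.15],
        [0.65, 0.25, 0.1],
        [0.7, 0.25, 0.05],
        [0.8, 0.15, 0.05],
        [0.55, 0.3, 0.15],
        [0.65, 0.25, 0.1]
      ]
    },
    {
      "child": "dispersibility",
      "parents": [
        "coating",
        "surface_charge"
      ],
      "prob": [
        [0.4, 0.6],
        [0.2, 0.8],
        [0.7, 0.3],
        [0.5, 0.5],
        [0.4, 0.6],
        [0.2, 0.8]
      ]
    },
    {
      "child": "cmr",
      "parents": [
        "morphology",
        "reactivity"
      ],
      "prob": [
        [0.9, 0.1],
        [0.3, 0.7],
        [0.5, 0.5],
        [0.1, 0.9]
      ]
    },
    {
      "child": "concentration",
      "parents": [
        "dispersibility",
        "solubility"
      ],
      "prob": [
        [0.352909550266885, 0.411677287108898, 0.177023114292396, 0.0485021084628648, 0.00876829031099069, 0.0010365939237702, 7.908405006396e-05, 3.97158413204047e-06],
        [0.0741843339851752, 0.290221987650995, 0.327264688953224, 0.204986324316589, 0.0799738179463816, 0.0198790575481822, 0.00315146448729997, 0.000338325112153242],
        [0.454177854394411, 0.383141310439, 0.129115436546949, 0.0288073940472917, 0.00430609920963498, 0.000423781312373528, 2.69963210336455e-05, 1.12772930642103e-06],
        [0.118413800842371, 0.347978797763852, 0.310862795170077, 0.159127124102136, 0.0514257827477851, 0.0106544090783702, 0.00141178843606105, 0.000125501859348207],
        [0.685354208783885, 0.257745230111878, 0.0493226565862741, 0.00686844436138445, 0.00066457760512284, 4.30173055872007e-05, 1.81529740428399e-06, 4.99484635184153e-08],
        [0.27923471389297, 0.416963030411802, 0.217012811005024, 0.0699097434027437, 0.014685966385102, 0.0020069032521387, 0.000176567720888365, 1.02639293318378e-05]
      ]
    },
    {
      "child": "oel",
      "parents": [
        "cmr"
      ],
      "prob": [
        [0.00589063969491595, 0.210113171157695, 0.612204092466397, 0.171792096680992],
        [0.390149487804053, 0.53686883509653, 0.0722624121102524, 0.000719264989163888]
      ]
    }
  ]
}
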