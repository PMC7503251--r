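{
  "name": "synthetic placeholder rules (not the Ministry of Health and Welfare table)",
  "levels": {
    "1": [
      {
        "feature": "gcs",
        "op": "le",
        "value": 8
      },
      {
        "feature": "spo2",
        "op": "lt",
        "value": 85
      },
      {
        "feature": "sbp",
        "op": "lt",
        "value": 70
      }
    ],
    "2": [
      {
        "feature": "gcs",
        "op": "le",
        "value": 12
      },
      {
        "feature": "spo2",
        "op": "lt",
        "value": 90
      },
      {
        "feature": "sbp",
        "op": "lt",
        "value": 90
      },
      {
        "feature": "sbp",
        "op": "gt",
        "value": 220
      },
      {
        "feature": "pulse",
        "op": "gt",
        "value": 140
      },
      {
        "feature": "resp",
        "op": "gt",
        "value": 35
      },
      {
        "feature": "temp",
        "op": "gt",
        "value": 41
      }
    ],
    "3": [
      {
        "feature": "gcs",
        "op": "le",
        "value": 14
      },
      {
        "feature": "spo2",
        "op": "lt",
        "value": 94
      },
      {
        "feature": "sbp",
        "op": "lt",
        "value": 100
      },
      {
        "feature": "sbp",
        "op": "gt",
        "value": 180
      },
      {
        "feature": "pulse",
        "op": "gt",
        "value": 120
      },
      {
        "feature": "pulse",
        "op": "lt",
        "value": 45
      },
      {
        "feature": "resp",
        "op": "gt",
        "value": 28
      },
      {
        "feature": "resp",
        "op": "lt",
        "value": 8
      },
      {
        "feature": "temp",
        "op": "gt",
        "value": 39
      },
      {
        "feature": "temp",
        "op": "lt",
        "value": 35
      },
      {
        "feature": "pain",
        "op": "ge",
        "value": 7
      }
    ],
    "4": [
      {
        "feature": "pain",
        "op": "ge",
        "value": 4
      },
      {
        "feature": "temp",
        "op": "gt",
        "value": 38
      },
      {
        "feature": "pulse",
        "op": "gt",
        "value": 100
      },
      {
        "feature": "sbp",
        "op": "gt",
        "value": 160
      },
      {
        "feature": "resp",
        "op": "gt",
        "value": 20
      }
    ]
  }
}
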