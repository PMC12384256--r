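{
  "version": "NIPP v2.2",
  "description": "Logistic NTCP model coefficients: NTCP = 1/(1+exp(-S)), S = intercept + sum(weight * Dmean) + baseline_offset. Predictor 'parotid_sum' is Dmean(parotid_l) + Dmean(parotid_r) as one summed term. Weights in 1/Gy; baseline offsets are fixed baseline-complaint terms.",
  "endpoints": {
    "Xer2+": {
      "intercept": -2.2951,
      "baseline_offset": 0.0,
      "weights": {
        "parotid_sum": 0.0996,
        "submandibular": 0.0182
      }
    },
    "Xer3+": {
      "intercept": -3.7286,
      "baseline_offset": 0.0,
      "weights": {
        "parotid_sum": 0.0855,
        "submandibular": 0.0156
      }
    },
    "Dys2+": {
      "intercept": -4.0536,
      "baseline_offset": -0.6281,
      "weights": {
        "oral_cavity": 0.030,
        "pcm_u": 0.0236,
        "pcm_m": 0.0095,
        "pcm_i": 0.0133
      }
    },
    "Dys3+": {
      "intercept": -7.674,
      "baseline_offset": 0.0387,
      "weights": {
        "oral_cavity": 0.0259,
        "pcm_u": 0.0203,
        "pcm_m": 0.0303,
        "pcm_i": 0.0341
      }
    }
  }
}
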