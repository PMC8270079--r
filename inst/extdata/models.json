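{
  "version": "nipp-hnc-revised-1.0",
  "models": [
    {
      "name": "xerostomia",
      "endpoint_label": "patient-rated moderate-to-severe xerostomia at 6 months",
      "ctcae_grade": 2,
      "intercept": -1.507,
      "dose_coefficients": {
        "parotid_contralateral_mean": 0.052
      },
      "clinical_coefficients": {
        "xer_baseline.minor": 0.525,
        "xer_baseline.moderate_severe": 1.482
      }
    },
    {
      "name": "dysphagia",
      "endpoint_label": "physician-rated grade II-IV dysphagia at 6 months",
      "ctcae_grade": 2,
      "intercept": -3.303,
      "dose_coefficients": {
        "oral_cavity_mean": 0.024,
        "pcm_superior_mean": 0.024
      },
      "clinical_coefficients": {
        "dysphagia_baseline_ge2": 0.967
      }
    },
    {
      "name": "tube_feeding",
      "endpoint_label": "tube feeding dependence at 6 months",
      "ctcae_grade": 3,
      "intercept": -6.849,
      "dose_coefficients": {
        "pcm_superior_mean": 0.030,
        "pcm_inferior_mean": 0.013,
        "parotid_contralateral_mean": 0.022,
        "cricopharyngeal_mean": 0.008
      },
      "clinical_coefficients": {
        "advanced_t_stage": 0.680,
        "weight_loss.moderate_1_10pct": 0.317,
        "weight_loss.severe_gt10pct": 1.178,
        "treatment.accelerated_rt": 0.198,
        "treatment.chemoradiation": 1.101,
        "treatment.rt_plus_cetuximab": 1.716
      }
    }
  ]
}
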