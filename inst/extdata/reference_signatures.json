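{
  "type": "habitomics_models",
  "version": 1,
  "cluster": null,
  "signatures": {
    "radiological": {
      "name": "radiological",
      "intercept": -3.164,
      "coefficients": {
        "solid_diameter": 0.162,
        "spl": 0.063
      },
      "cutoff": 0.348,
      "z_mean": null,
      "z_sd": null
    },
    "radiomic": {
      "name": "radiomic",
      "intercept": -0.876,
      "coefficients": {
        "GLCM_ClusterShade": -1.036,
        "GLDM_LargeDependenceEmphasis": 0.621,
        "GLDM_LargeDependenceLowGrayLevelEmphasis": -1.864
      },
      "cutoff": 0.358,
      "z_mean": null,
      "z_sd": null
    },
    "habitat": {
      "name": "habitat",
      "intercept": -1.032,
      "coefficients": {
        "Habitat1_firstorder_Skewness": -0.706,
        "Habitat1_GLDM_SmallDependenceEmphasis": 0.504,
        "Habitat2_NGTDM_Busyness": -1.234,
        "Habitat3_GLCM_ClusterProminence": -0.826,
        "Habitat3_NGTDM_Contrast": -0.712
      },
      "cutoff": 0.476,
      "z_mean": null,
      "z_sd": null
    }
  }
}
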