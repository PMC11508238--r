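{
  "annotations": {
    "patient": 2062,
    "clinician": 2048,
    "visitor": 1564
  },
  "images_cleaned": 2130,
  "images_excluded": 244,
  "train_fraction": 0.8,
  "assessments": {
    "non_delirious": 125,
    "delirious": 29
  }
}
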