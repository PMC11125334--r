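{
  "anova_f": 28.731,
  "anova_p": 2.346e-09,
  "tukey_lstm_to_icgn": 6.39,
  "tukey_bilstm_to_icgn": 2.437,
  "tukey_bilstm_to_lstm": -3.953,
  "lstm_mean": 84.89,
  "lstm_sd": 3.91,
  "icgn_sd": 1.60,
  "bilstm_sd": 1.96
}
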