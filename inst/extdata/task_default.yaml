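n_trials: 120
presentations_per_deck: 30
starting_bank: 2000.0
timeout_seconds: 4.0
version: 1
timeout_prob: 0.0
presentation_order: BDDDCDDBDABDADACCBDCDDACACBBDDDBDDDDBCDDBCABCBCCABBDCBBDDACBCABCBACAAAADBCDCBAABBCABDBACACAABDBBAACCACDCBDCAAACDACABCBCA
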