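outcome	n_cases	n_controls
coronary_artery_disease	11802	137950
ischemic_stroke	4678	12863
type_2_diabetes	30053	434336
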