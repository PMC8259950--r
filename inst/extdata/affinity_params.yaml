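# Default parameters of the TBP-promoter affinity model, version 1.
# Calibrated once on the packaged synthetic-promoter generator so that
# consensus-damaging core substitutions are called "deficiency" at alpha.
version: 1
w0: 23.0
w_pwm: 0.4
w_ta: 0.35
w_mg: 0.15
w_melt: 0.25
L: 15
pseudocount: 0.5
scan_both_strands: true
top_k_for_se: 20
alpha: 0.05
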