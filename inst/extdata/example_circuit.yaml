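# Example circuit: 18 Fr drainage / 14 Fr return at 3000 rpm, bed raised
# 40 cm above pump level, bench CVP of 0 mmHg (open bath).
drainage_side: [drain_18fr, tube1]
pump: centrifugal
rpm: 3000
return_side: [tube2, oxygenator, tube3, return_14fr]
cvp_mmhg: 0
bed_height_cm: 40
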