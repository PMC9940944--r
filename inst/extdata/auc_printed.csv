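system,auc,ci_low,ci_high
FIGO,0.73,0.63,0.84
RCOG,0.72,0.60,0.80
NICHD,0.69,0.57,0.80
PARER,0.96,0.91,1.00
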