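system,category,sensitivity,specificity,lr_pos,lr_neg,ppv,npv
FIGO,normal,95.3,32.6,1.41,0.14,58.6,87.5
FIGO,suspicious,44.2,48.8,0.86,1.14,46.3,46.5
FIGO,pathological,51.2,83.7,3.14,0.58,75.9,67.4
RCOG,normal,95.3,51.2,1.95,0.09,66.1,91.7
RCOG,suspicious,20.9,93,3,0.85,75,54
RCOG,pathological,74.4,58.1,1.78,0.44,64,69.4
NICHD,I,95.4,4.7,1,1,50,50
NICHD,II,55.8,95.3,12,0.46,92.3,68.3
NICHD,III,39.5,100,NA,0.6,100,62.3
PARER,green,95.4,76.7,4.1,0.06,80.4,94.3
PARER,blue,100,81.4,5.4,0,84.3,100
PARER,yellow,30.2,97.6,13.0,0.7,92.9,58.3
PARER,orange,39.5,97.7,17.0,0.6,94.4,61.7
PARER,red,25.6,100,NA,0.4,100,57.3
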