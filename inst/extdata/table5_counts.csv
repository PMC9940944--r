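system,category,cases,controls
FIGO,normal,2,14
FIGO,suspicious,19,22
FIGO,pathological,22,7
RCOG,normal,2,22
RCOG,suspicious,9,3
RCOG,pathological,32,18
NICHD,I,2,2
NICHD,II,24,41
NICHD,III,17,0
PARER,green,2,33
PARER,blue,0,8
PARER,yellow,13,1
PARER,orange,17,1
PARER,red,11,0
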