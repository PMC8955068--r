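run,GMS,poloxamer407,oleic_acid,PS,EE,ZP,CDR
1,100,1.5,30,115.8,75.2,-28.4,84.3
2,150,1,15,180.0,67.8,-28.3,54.2
3,150,1.5,22.5,157.7,78.9,-30.8,69.8
4,150,2,30,141.9,81.3,-34.9,89.6
5,150,1.5,22.5,161.6,81.4,-30.2,70.3
6,100,2,22.5,107.2,59.5,-29.6,78.6
7,200,2,22.5,203.2,83.8,-29.9,75.4
8,150,1.5,22.5,167.0,83.2,-34.8,72.3
9,150,1.5,22.5,168.4,82.9,-30.7,71.3
10,100,1,22.5,132.0,61.8,-31.5,66.9
11,150,1,30,175.0,85.3,-29.8,80.5
12,200,1,22.5,230.8,91.4,-31.3,65.7
13,200,1.5,30,211.6,89.5,-35.1,82.5
14,100,1.5,15,125.4,54.1,-33.1,59.3
15,200,1.5,15,218.7,86.9,-27.5,57.3
16,150,2,15,148.0,65.4,-32.1,61.4
17,150,1.5,22.5,171.3,84.3,-28.9,71.8
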