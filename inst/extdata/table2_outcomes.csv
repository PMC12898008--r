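id,margin_mm,operative_time_min,blood_loss_ml,msts,recurrence,metastasis,status
1,20,280,1000,21,No,No,Live
2,20,375,2000,30,No,Yes,Dead
3,20,180,800,25,No,No,Live
4,15,300,2400,27,No,No,Live
5,20,240,1000,30,No,No,Live
6,20,160,800,27,No,Yes,Dead
7,10,360,1500,26,No,No,Live
8,10,150,1200,27,No,No,Live
9,20,150,1200,28,No,No,Live
10,20,185,500,27,No,No,Live
11,20,344,2500,26,No,No,Live
12,20,180,400,28,No,No,Live
13,20,240,1400,27,No,No,Live
14,20,180,400,NA,No,No,Live
15,20,570,3000,28,No,No,Live
16,15,165,1200,27,No,No,Live
17,10,120,1000,27,No,No,Live
18,20,340,1000,25,No,No,Live
19,20,270,2500,26,No,No,Live
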