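id,age,gender,tumor_position,histological_grade,tumor_type,follow_up_months
1,60,male,type IV,IIB,chordoma,86
2,56,male,type II + III,IIB,osteosarcoma,17
3,39,female,type I,IIB,peripheral nerve sheath tumor,62
4,51,female,type II + III,3,giant cell tumor,62
5,66,male,type III,IIB,spindle cell sarcoma,54
6,46,female,type II,IIB,chondrosarcoma,50
7,45,female,type I + II,3,giant cell tumor,47
8,57,female,type I,3,giant cell tumor,43
9,45,female,type III,IB,chondrosarcoma,35
10,40,female,type III,IB,chondrosarcoma,31
11,22,female,type II + III,IIB,Ewing sarcoma,31
12,49,female,type I,3,Chondromyxoid fibroma,28
13,39,female,type III,IB,chondrosarcoma,26
14,57,male,type I + II,IB,chondrosarcoma,25
15,19,male,type I,IIB,Ewing sarcoma,25
16,49,male,type IV,IB,chordoma,20
17,37,male,type III,3,giant cell tumor,20
18,29,female,type II + III,IIB,Ewing sarcoma,18
19,50,male,type II,IB,chondrosarcoma,14
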