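monkey,scene,total,accept,return,stay,other,fixbreak
C,1,1479,0,1113,314,28,24
C,2,1409,1,1100,284,15,9
C,3,1396,6,1282,94,9,5
C,4,1473,6,1253,167,13,34
S,1,1602,3,1188,376,30,5
S,2,1504,2,1063,426,6,7
S,3,1475,1,1176,287,7,4
S,4,1446,5,1130,291,15,5
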