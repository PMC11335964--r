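alias,channel,distance
P7,D31,0.1642
P8,B11,0.1573
PO7,A10,0.1305
PO8,B7,0.1249
P9,A12,0.1518
P10,B9,0.1540
O1,A16,0.1143
O2,A29,0.1124
Oz,A22,0.0477
POz,A21,0.0933
Pz,A19,0.0268
CPz,A3,0.0429
Cz,A1,0.0912
Fz,C21,0.0810
T7,D24,0.1456
T8,B14,0.1576
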