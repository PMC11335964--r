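name,x,y,z,x2d,y2d
A1,0.000000,0.000000,1.000000,0.000000,0.000000
A2,0.000000,-0.190809,0.981627,0.000000,-0.191986
A3,0.000000,-0.390731,0.920505,0.000000,-0.401426
A4,0.000000,-0.559193,0.829038,0.000000,-0.593412
A5,-0.281068,-0.662156,0.694658,-0.313699,-0.739029
A6,-0.508650,-0.508650,0.694658,-0.567702,-0.567702
A7,-0.593030,-0.593030,0.544639,-0.703456,-0.703456
A8,-0.548745,-0.755282,0.358368,-0.707856,-0.974281
A9,-0.578855,-0.796726,0.173648,-0.820703,-1.129601
A10,-0.587427,-0.808524,-0.034899,-0.943808,-1.299041
A11,-0.572720,-0.788282,-0.224951,-1.056655,-1.454361
A12,-0.532714,-0.733218,-0.422618,-1.179761,-1.623801
A13,-0.280065,-0.861950,-0.422618,-0.620237,-1.908893
A14,-0.301097,-0.926681,-0.224951,-0.555516,-1.709704
A15,-0.308829,-0.950477,-0.034899,-0.496189,-1.527114
A16,-0.304322,-0.936608,0.173648,-0.431469,-1.327925
A17,-0.288492,-0.887888,0.358368,-0.372142,-1.145336
A18,-0.327695,-0.772000,0.544639,-0.388714,-0.915753
A19,0.000000,-0.719340,0.694658,0.000000,-0.802851
A20,0.000000,-0.838671,0.544639,0.000000,-0.994838
A21,0.000000,-0.933580,0.358368,0.000000,-1.204277
A22,0.000000,-0.984808,0.173648,0.000000,-1.396263
A23,0.000000,-0.999391,-0.034899,0.000000,-1.605703
A24,0.000000,-0.974370,-0.224951,0.000000,-1.797689
A25,0.000000,-0.906308,-0.422618,0.000000,-2.007129
A26,0.280065,-0.861950,-0.422618,0.620237,-1.908893
A27,0.301097,-0.926681,-0.224951,0.555516,-1.709704
A28,0.308829,-0.950477,-0.034899,0.496189,-1.527114
A29,0.304322,-0.936608,0.173648,0.431469,-1.327925
A30,0.288492,-0.887888,0.358368,0.372142,-1.145336
A31,0.327695,-0.772000,0.544639,0.388714,-0.915753
A32,0.281068,-0.662156,0.694658,0.313699,-0.739029
B1,0.181470,-0.058963,0.981627,0.182590,-0.059327
B2,0.276289,-0.276289,0.920505,0.283851,-0.283851
B3,0.508650,-0.508650,0.694658,0.567702,-0.567702
B4,0.593030,-0.593030,0.544639,0.703456,-0.703456
B5,0.548745,-0.755282,0.358368,0.707856,-0.974281
B6,0.578855,-0.796726,0.173648,0.820703,-1.129601
B7,0.587427,-0.808524,-0.034899,0.943808,-1.299041
B8,0.572720,-0.788282,-0.224951,1.056655,-1.454361
B9,0.532714,-0.733218,-0.422618,1.179761,-1.623801
B10,0.788282,-0.572720,-0.224951,1.454361,-1.056655
B11,0.808524,-0.587427,-0.034899,1.299041,-0.943808
B12,0.796726,-0.578855,0.173648,1.129601,-0.820703
B13,0.755282,-0.548745,0.358368,0.974281,-0.707856
B14,0.950477,-0.308829,-0.034899,1.527114,-0.496189
B15,0.936608,-0.304322,0.173648,1.327925,-0.431469
B16,0.887888,-0.288492,0.358368,1.145336,-0.372142
B17,0.777602,-0.314172,0.544639,0.922397,-0.372673
B18,0.666960,-0.269469,0.694658,0.744391,-0.300753
B19,0.484275,-0.279596,0.829038,0.513910,-0.296706
B20,0.390731,0.000000,0.920505,0.401426,0.000000
B21,0.559193,0.000000,0.829038,0.593412,0.000000
B22,0.719340,0.000000,0.694658,0.802851,0.000000
B23,0.838671,0.000000,0.544639,0.994838,0.000000
B24,0.933580,0.000000,0.358368,1.204277,0.000000
B25,0.984808,0.000000,0.173648,1.396263,0.000000
B26,0.999391,0.000000,-0.034899,1.605703,0.000000
B27,0.950477,0.308829,-0.034899,1.527114,0.496189
B28,0.936608,0.304322,0.173648,1.327925,0.431469
B29,0.887888,0.288492,0.358368,1.145336,0.372142
B30,0.777602,0.314172,0.544639,0.922397,0.372673
B31,0.666960,0.269469,0.694658,0.744391,0.300753
B32,0.484275,0.279596,0.829038,0.513910,0.296706
C1,0.112155,0.154368,0.981627,0.112847,0.155320
C2,0.276289,0.276289,0.920505,0.283851,0.283851
C3,0.508650,0.508650,0.694658,0.567702,0.567702
C4,0.593030,0.593030,0.544639,0.703456,0.703456
C5,0.755282,0.548745,0.358368,0.974281,0.707856
C6,0.796726,0.578855,0.173648,1.129601,0.820703
C7,0.808524,0.587427,-0.034899,1.299041,0.943808
C8,0.587427,0.808524,-0.034899,0.943808,1.299041
C9,0.578855,0.796726,0.173648,0.820703,1.129601
C10,0.548745,0.755282,0.358368,0.707856,0.974281
C11,0.279596,0.484275,0.829038,0.296706,0.513910
C12,0.281068,0.662156,0.694658,0.313699,0.739029
C13,0.327695,0.772000,0.544639,0.388714,0.915753
C14,0.288492,0.887888,0.358368,0.372142,1.145336
C15,0.304322,0.936608,0.173648,0.431469,1.327925
C16,0.308829,0.950477,-0.034899,0.496189,1.527114
C17,0.000000,0.999391,-0.034899,0.000000,1.605703
C18,0.000000,0.984808,0.173648,0.000000,1.396263
C19,0.000000,0.933580,0.358368,0.000000,1.204277
C20,0.000000,0.838671,0.544639,0.000000,0.994838
C21,0.000000,0.719340,0.694658,0.000000,0.802851
C22,0.000000,0.559193,0.829038,0.000000,0.593412
C23,0.000000,0.390731,0.920505,0.000000,0.401426
C24,-0.279596,0.484275,0.829038,-0.296706,0.513910
C25,-0.281068,0.662156,0.694658,-0.313699,0.739029
C26,-0.327695,0.772000,0.544639,-0.388714,0.915753
C27,-0.288492,0.887888,0.358368,-0.372142,1.145336
C28,-0.304322,0.936608,0.173648,-0.431469,1.327925
C29,-0.308829,0.950477,-0.034899,-0.496189,1.527114
C30,-0.587427,0.808524,-0.034899,-0.943808,1.299041
C31,-0.578855,0.796726,0.173648,-0.820703,1.129601
C32,-0.548745,0.755282,0.358368,-0.707856,0.974281
D1,-0.112155,0.154368,0.981627,-0.112847,0.155320
D2,-0.276289,0.276289,0.920505,-0.283851,0.283851
D3,-0.508650,0.508650,0.694658,-0.567702,0.567702
D4,-0.593030,0.593030,0.544639,-0.703456,0.703456
D5,-0.755282,0.548745,0.358368,-0.974281,0.707856
D6,-0.796726,0.578855,0.173648,-1.129601,0.820703
D7,-0.808524,0.587427,-0.034899,-1.299041,0.943808
D8,-0.950477,0.308829,-0.034899,-1.527114,0.496189
D9,-0.936608,0.304322,0.173648,-1.327925,0.431469
D10,-0.887888,0.288492,0.358368,-1.145336,0.372142
D11,-0.777602,0.314172,0.544639,-0.922397,0.372673
D12,-0.666960,0.269469,0.694658,-0.744391,0.300753
D13,-0.484275,0.279596,0.829038,-0.513910,0.296706
D14,-0.390731,-0.000000,0.920505,-0.401426,-0.000000
D15,-0.181470,-0.058963,0.981627,-0.182590,-0.059327
D16,-0.276289,-0.276289,0.920505,-0.283851,-0.283851
D17,-0.484275,-0.279596,0.829038,-0.513910,-0.296706
D18,-0.559193,-0.000000,0.829038,-0.593412,-0.000000
D19,-0.719340,-0.000000,0.694658,-0.802851,-0.000000
D20,-0.838671,-0.000000,0.544639,-0.994838,-0.000000
D21,-0.933580,-0.000000,0.358368,-1.204277,-0.000000
D22,-0.984808,-0.000000,0.173648,-1.396263,-0.000000
D23,-0.999391,-0.000000,-0.034899,-1.605703,-0.000000
D24,-0.950477,-0.308829,-0.034899,-1.527114,-0.496189
D25,-0.936608,-0.304322,0.173648,-1.327925,-0.431469
D26,-0.887888,-0.288492,0.358368,-1.145336,-0.372142
D27,-0.777602,-0.314172,0.544639,-0.922397,-0.372673
D28,-0.666960,-0.269469,0.694658,-0.744391,-0.300753
D29,-0.755282,-0.548745,0.358368,-0.974281,-0.707856
D30,-0.796726,-0.578855,0.173648,-1.129601,-0.820703
D31,-0.808524,-0.587427,-0.034899,-1.299041,-0.943808
D32,-0.788282,-0.572720,-0.224951,-1.454361,-1.056655
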