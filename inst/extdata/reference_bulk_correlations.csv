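fa,r_13C,r_2H
14:0,0.734,0.313
16:0,0.925,0.778
16:1,0.700,0.696
18:0,0.851,0.833
18:1,0.908,0.826
LIN,0.610,0.217
ALA,0.645,-0.122
SDA,0.443,0.217
ARA,0.635,-0.449
ETA,0.630,0.392
EPA,0.808,0.385
DPA,0.728,0.620
DHA,0.897,0.375
FA_Bulk,1.000,1.000
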