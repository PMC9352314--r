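fa,isotope,tissue,R,se
14:0,13C,brain,0.33,0.11
14:0,13C,eye,0.61,0.12
14:0,13C,liver,0.16,0.09
14:0,13C,muscle,0.60,0.12
14:0,2H,brain,0.59,0.12
14:0,2H,eye,0.45,0.12
14:0,2H,liver,0.37,0.13
14:0,2H,muscle,0.33,0.11
16:0,13C,brain,0.71,0.10
16:0,13C,eye,0.61,0.12
16:0,13C,liver,0.62,0.12
16:0,13C,muscle,0.81,0.08
16:0,2H,brain,0.50,0.12
16:0,2H,eye,0.42,0.12
16:0,2H,liver,0.38,0.13
16:0,2H,muscle,0.44,0.12
16:1,13C,brain,0.63,0.11
16:1,13C,eye,0.45,0.12
16:1,13C,liver,0.38,0.13
16:1,13C,muscle,0.56,0.12
16:1,2H,brain,0.41,0.12
16:1,2H,eye,0.33,0.12
16:1,2H,liver,0.31,0.13
16:1,2H,muscle,0.15,0.08
18:0,13C,brain,0.60,0.12
18:0,13C,eye,0.59,0.12
18:0,13C,liver,0.49,0.14
18:0,13C,muscle,0.59,0.12
18:0,2H,brain,0.39,0.12
18:0,2H,eye,0.35,0.11
18:0,2H,liver,0.52,0.13
18:0,2H,muscle,0.12,0.07
18:1,13C,brain,0.74,0.10
18:1,13C,eye,0.71,0.10
18:1,13C,liver,0.45,0.14
18:1,13C,muscle,0.70,0.10
18:1,2H,brain,0.30,0.11
18:1,2H,eye,0.32,0.12
18:1,2H,liver,0.23,0.11
18:1,2H,muscle,0.20,0.09
LIN,13C,brain,0.37,0.12
LIN,13C,eye,0.55,0.13
LIN,13C,liver,0.38,0.13
LIN,13C,muscle,0.43,0.12
LIN,2H,brain,0.19,0.09
LIN,2H,eye,0.32,0.11
LIN,2H,liver,0.27,0.12
LIN,2H,muscle,0.59,0.12
ALA,13C,brain,0.56,0.12
ALA,13C,eye,0.65,0.11
ALA,13C,liver,0.59,0.13
ALA,13C,muscle,0.76,0.09
ALA,2H,brain,0.43,0.12
ALA,2H,eye,0.58,0.12
ALA,2H,liver,0.47,0.13
ALA,2H,muscle,0.67,0.11
SDA,13C,brain,0.62,0.12
SDA,13C,eye,0.37,0.12
SDA,13C,liver,0.26,0.12
SDA,13C,muscle,0.25,0.10
SDA,2H,brain,0.18,0.12
SDA,2H,eye,0.18,0.09
SDA,2H,liver,0.13,0.10
SDA,2H,muscle,0.10,0.07
ARA,13C,brain,0.52,0.12
ARA,13C,eye,0.63,0.12
ARA,13C,liver,0.40,0.13
ARA,13C,muscle,0.59,0.12
ARA,2H,brain,0.38,0.12
ARA,2H,eye,0.40,0.12
ARA,2H,liver,0.46,0.14
ARA,2H,muscle,0.42,0.12
ETA,13C,brain,0.58,0.12
ETA,13C,eye,0.60,0.12
ETA,13C,liver,0.63,0.12
ETA,13C,muscle,0.56,0.12
ETA,2H,brain,0.08,0.07
ETA,2H,eye,0.49,0.14
ETA,2H,liver,0.12,0.10
ETA,2H,muscle,0.16,0.09
EPA,13C,brain,0.79,0.09
EPA,13C,eye,0.55,0.12
EPA,13C,liver,0.63,0.12
EPA,13C,muscle,0.80,0.09
EPA,2H,brain,0.45,0.12
EPA,2H,eye,0.52,0.12
EPA,2H,liver,0.37,0.13
EPA,2H,muscle,0.29,0.11
DPA,13C,brain,0.74,0.10
DPA,13C,eye,0.41,0.12
DPA,13C,liver,0.57,0.13
DPA,13C,muscle,0.80,0.09
DPA,2H,brain,0.43,0.12
DPA,2H,eye,0.49,0.13
DPA,2H,liver,0.36,0.13
DPA,2H,muscle,0.20,0.10
DHA,13C,brain,0.84,0.07
DHA,13C,eye,0.76,0.09
DHA,13C,liver,0.66,0.12
DHA,13C,muscle,0.79,0.09
DHA,2H,brain,0.34,0.11
DHA,2H,eye,0.28,0.11
DHA,2H,liver,0.52,0.13
DHA,2H,muscle,0.24,0.10
FA_Bulk,13C,brain,0.83,0.07
FA_Bulk,13C,eye,0.68,0.11
FA_Bulk,13C,liver,0.66,0.11
FA_Bulk,13C,muscle,0.80,0.08
FA_Bulk,2H,brain,0.41,0.11
FA_Bulk,2H,eye,0.42,0.11
FA_Bulk,2H,liver,0.51,0.12
FA_Bulk,2H,muscle,0.35,0.10
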