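time_ms,mean_z_sdtheta1,mean_z_sdtheta2,sd_z_sdtheta1,sd_z_sdtheta2
-40,0.308,0.121,0.475,0.823
-39,0.345,0.177,0.459,0.828
-38,0.379,0.230,0.441,0.831
-37,0.409,0.279,0.435,0.826
-36,0.435,0.324,0.457,0.795
-35,0.456,0.363,0.503,0.717
-34,0.474,0.399,0.557,0.600
-33,0.488,0.430,0.608,0.482
-32,0.501,0.458,0.643,0.381
-31,0.511,0.481,0.652,0.299
-30,0.520,0.502,0.636,0.232
-29,0.527,0.520,0.599,0.178
-28,0.533,0.535,0.547,0.135
-27,0.537,0.549,0.485,0.102
-26,0.540,0.561,0.415,0.073
-25,0.541,0.572,0.340,0.047
-24,0.541,0.582,0.267,0.019
-23,0.538,0.592,0.200,-0.009
-22,0.535,0.601,0.146,-0.037
-21,0.530,0.610,0.113,-0.061
-20,0.524,0.618,0.106,-0.075
-19,0.517,0.625,0.126,-0.074
-18,0.510,0.632,0.168,-0.053
-17,0.503,0.638,0.220,-0.012
-16,0.495,0.643,0.267,0.041
-15,0.486,0.648,0.296,0.095
-14,0.474,0.651,0.309,0.136
-13,0.459,0.653,0.317,0.162
-12,0.439,0.651,0.341,0.178
-11,0.413,0.644,0.391,0.183
-10,0.382,0.633,0.453,0.171
-9,0.346,0.615,0.501,0.147
-8,0.306,0.593,0.529,0.126
-7,0.267,0.566,0.536,0.111
-6,0.232,0.536,0.524,0.102
-5,0.205,0.504,0.488,0.098
-4,0.190,0.472,0.415,0.092
-3,0.190,0.437,0.303,0.078
-2,0.207,0.401,0.195,0.057
-1,0.244,0.364,0.132,0.041
0,0.298,0.327,0.116,0.039
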