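pitcher,handedness,speed_mean,speed_sd,theta1_deg_mean,theta1_deg_sd,theta2_deg_mean,theta2_deg_sd,x_mean,x_sd,y_mean,y_sd,z_mean,z_sd
A,right,32.49,0.85,1.51,0.89,-5.95,0.99,0.47,0.03,1.42,0.05,1.53,0.03
B,right,29.66,0.70,-0.90,1.08,-7.52,0.84,0.40,0.02,1.77,0.03,1.67,0.01
C,right,26.82,0.58,1.67,1.81,-3.42,0.55,0.44,0.01,1.29,0.04,1.76,0.02
D,right,32.19,0.62,-1.53,0.84,-4.08,0.60,0.36,0.02,1.24,0.05,1.75,0.03
E,right,26.83,0.74,1.36,1.59,-4.16,0.97,0.49,0.04,1.42,0.04,1.72,0.02
F,right,35.14,0.23,0.72,1.17,-3.11,0.58,0.40,0.02,1.58,0.02,1.54,0.02
G,right,33.12,0.41,2.81,0.74,-5.72,0.45,1.02,0.02,1.46,0.02,1.46,0.01
H,right,26.90,0.58,-2.98,1.30,-6.08,1.37,0.39,0.02,1.72,0.03,1.78,0.01
I,right,29.77,1.53,0.13,1.48,-9.06,0.88,0.38,0.03,1.35,0.11,1.68,0.03
J,right,32.85,1.05,-7.65,1.75,-2.79,1.97,0.13,0.07,1.44,0.03,1.85,0.02
K,right,32.53,0.51,2.52,1.46,-2.56,0.74,0.25,0.03,1.49,0.04,1.55,0.02
L,right,30.11,0.30,0.06,1.67,-4.70,0.76,0.49,0.03,1.57,0.02,1.65,0.02
M,right,30.81,0.28,0.71,1.44,-3.51,0.98,0.41,0.03,1.75,0.03,1.44,0.01
N,left,32.52,0.45,-0.44,0.97,-6.14,0.70,0.17,0.03,1.76,0.03,1.76,0.01
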