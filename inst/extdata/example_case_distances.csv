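case,depthanything_mean,depthanything_sd,superglue_mean,superglue_sd,segmentdepth_mean,segmentdepth_sd,bboxdepth_mean,bboxdepth_sd,reference_mean,reference_sd
BY,1.80,0.25,1.55,0.44,1.72,0.53,1.73,0.54,1.72,0.21
BW,1.51,0.21,1.15,0.33,1.19,0.36,1.19,0.37,0.93,0.06
CY,1.59,0.20,1.34,0.48,1.46,0.59,1.47,0.59,1.72,0.26
CW,1.58,0.30,1.05,0.26,1.06,0.28,1.06,0.28,0.99,0.04
SY,1.65,0.30,1.38,0.54,1.64,0.79,1.64,0.79,1.23,0.25
SW,1.44,0.27,0.91,0.41,1.00,0.54,0.95,0.53,0.77,0.05
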