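id,superglue,segmentdepth,bboxdepth,depthanything
628,2.174,3.748,2.734,2.302
652,1.582,1.898,1.960,2.844
670,2.017,2.015,1.659,1.896
683,1.350,1.378,1.414,2.114
685,0.670,0.678,0.717,1.381
695,2.244,2.221,2.262,2.397
696,1.062,0.739,1.011,1.300
697,1.514,1.471,1.630,2.848
699,1.933,1.955,2.227,3.400
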