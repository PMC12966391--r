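weighting,metric,ba_bias,loa_low,loa_high,icc
FA,density,-0.022,-0.046,0.003,0.86
FA,efficiency,-0.013,-0.02,-0.006,0.69
FA,modularity,0.006,-0.003,0.015,0.93
FA,clustering,-0.008,-0.039,0.022,0.78
FA,strength,-1.498,-2.156,-0.84,0.76
MD,density,-0.022,-0.046,0.003,0.86
MD,efficiency,-0.092,-0.173,-0.01,0.83
MD,modularity,0.008,-0.013,0.029,0.88
MD,clustering,-0.012,-0.028,0.003,0.88
MD,strength,-14.27,-28.798,0.259,0.85
INVF,density,-0.022,-0.046,0.003,0.86
INVF,efficiency,-0.009,-0.015,-0.004,0.68
INVF,modularity,0.008,-0.009,0.026,0.89
INVF,clustering,-0.037,-0.156,0.082,0.12
INVF,strength,-1.292,-2.018,-0.567,0.76
ECVF,density,-0.022,-0.046,0.003,0.86
ECVF,efficiency,-0.215,-0.409,-0.021,0.13
ECVF,modularity,0.01,-0.01,0.03,0.88
ECVF,clustering,-0.029,-0.073,0.016,0.49
ECVF,strength,-18.949,-32.695,-5.203,0.37
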