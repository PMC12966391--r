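weighting,metric,subject,cv_percent
FA,density,HV1,0.47
FA,density,HV2,0.96
FA,density,HV3,2.36
FA,density,HV4,1.69
FA,efficiency,HV1,1.52
FA,efficiency,HV2,1.3
FA,efficiency,HV3,1.04
FA,efficiency,HV4,1.94
FA,modularity,HV1,3.27
FA,modularity,HV2,8.27
FA,modularity,HV3,7.1
FA,modularity,HV4,2.63
FA,clustering,HV1,0.65
FA,clustering,HV2,1.19
FA,clustering,HV3,2.15
FA,clustering,HV4,1.24
FA,strength,HV1,1.83
FA,strength,HV2,1.94
FA,strength,HV3,2.52
FA,strength,HV4,2.94
MD,density,HV1,0.47
MD,density,HV2,0.96
MD,density,HV3,2.36
MD,density,HV4,1.69
MD,efficiency,HV1,0.33
MD,efficiency,HV2,0.54
MD,efficiency,HV3,1.06
MD,efficiency,HV4,0.81
MD,modularity,HV1,3.75
MD,modularity,HV2,3.62
MD,modularity,HV3,8.91
MD,modularity,HV4,15.42
MD,clustering,HV1,0.42
MD,clustering,HV2,0.43
MD,clustering,HV3,1.44
MD,clustering,HV4,0.68
MD,strength,HV1,0.58
MD,strength,HV2,1.08
MD,strength,HV3,2.41
MD,strength,HV4,1.74
INVF,density,HV1,0.47
INVF,density,HV2,0.96
INVF,density,HV3,2.36
INVF,density,HV4,1.69
INVF,efficiency,HV1,1.22
INVF,efficiency,HV2,0.56
INVF,efficiency,HV3,0.95
INVF,efficiency,HV4,0.85
INVF,modularity,HV1,2.46
INVF,modularity,HV2,0.45
INVF,modularity,HV3,10.42
INVF,modularity,HV4,15.83
INVF,clustering,HV1,6.33
INVF,clustering,HV2,0.22
INVF,clustering,HV3,8.98
INVF,clustering,HV4,1.91
INVF,strength,HV1,1.54
INVF,strength,HV2,1.13
INVF,strength,HV3,2.44
INVF,strength,HV4,1.79
ECVF,density,HV1,0.47
ECVF,density,HV2,0.96
ECVF,density,HV3,2.36
ECVF,density,HV4,1.69
ECVF,efficiency,HV1,3.2
ECVF,efficiency,HV2,5.77
ECVF,efficiency,HV3,2.16
ECVF,efficiency,HV4,6.16
ECVF,modularity,HV1,1.1
ECVF,modularity,HV2,0.24
ECVF,modularity,HV3,7
ECVF,modularity,HV4,13.63
ECVF,clustering,HV1,0.78
ECVF,clustering,HV2,6.1
ECVF,clustering,HV3,1.73
ECVF,clustering,HV4,2.84
ECVF,strength,HV1,3.53
ECVF,strength,HV2,6.65
ECVF,strength,HV3,3.78
ECVF,strength,HV4,7.32
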