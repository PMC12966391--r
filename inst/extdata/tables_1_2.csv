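weighting,metric,subject,site1,site2
FA,density,HV1,0.859,0.867
FA,density,HV2,0.771,0.785
FA,density,HV3,0.748,0.784
FA,density,HV4,0.795,0.822
FA,efficiency,HV1,0.447,0.461
FA,efficiency,HV2,0.449,0.461
FA,efficiency,HV3,0.423,0.432
FA,efficiency,HV4,0.45,0.467
FA,modularity,HV1,0.032,0.031
FA,modularity,HV2,0.061,0.051
FA,modularity,HV3,0.08,0.07
FA,modularity,HV4,0.045,0.043
FA,clustering,HV1,0.593,0.601
FA,clustering,HV2,0.551,0.538
FA,clustering,HV3,0.545,0.568
FA,clustering,HV4,0.556,0.571
FA,strength,HV1,33.835,35.096
FA,strength,HV2,31.658,32.908
FA,strength,HV3,29.273,30.788
FA,strength,HV4,32.481,34.448
MD,density,HV1,0.859,0.867
MD,density,HV2,0.771,0.785
MD,density,HV3,0.748,0.784
MD,density,HV4,0.795,0.822
MD,efficiency,HV1,6.932,6.977
MD,efficiency,HV2,6.628,6.7
MD,efficiency,HV3,6.537,6.678
MD,efficiency,HV4,6.729,6.839
MD,modularity,HV1,0.042,0.039
MD,modularity,HV2,0.063,0.068
MD,modularity,HV3,0.103,0.086
MD,modularity,HV4,0.062,0.045
MD,clustering,HV1,0.875,0.883
MD,clustering,HV2,0.829,0.836
MD,clustering,HV3,0.807,0.83
MD,clustering,HV4,0.853,0.864
MD,strength,HV1,531.167,537.376
MD,strength,HV2,478.243,488.669
MD,strength,HV3,463.579,486.467
MD,strength,HV4,494.266,511.822
INVF,density,HV1,0.859,0.867
INVF,density,HV2,0.771,0.785
INVF,density,HV3,0.748,0.784
INVF,density,HV4,0.795,0.822
INVF,efficiency,HV1,0.512,0.525
INVF,efficiency,HV2,0.517,0.523
INVF,efficiency,HV3,0.496,0.505
INVF,efficiency,HV4,0.517,0.526
INVF,modularity,HV1,0.03,0.029
INVF,modularity,HV2,0.056,0.055
INVF,modularity,HV3,0.092,0.075
INVF,modularity,HV4,0.052,0.038
INVF,clustering,HV1,0.525,0.596
INVF,clustering,HV2,0.606,0.604
INVF,clustering,HV3,0.529,0.633
INVF,clustering,HV4,0.653,0.629
INVF,strength,HV1,38.923,40.144
INVF,strength,HV2,36.925,37.766
INVF,strength,HV3,34.674,36.41
INVF,strength,HV4,37.641,39.013
ECVF,density,HV1,0.859,0.867
ECVF,density,HV2,0.771,0.785
ECVF,density,HV3,0.748,0.784
ECVF,density,HV4,0.795,0.822
ECVF,efficiency,HV1,2.46,2.622
ECVF,efficiency,HV2,2.334,2.62
ECVF,efficiency,HV3,2.306,2.408
ECVF,efficiency,HV4,2.354,2.663
ECVF,modularity,HV1,0.07,0.069
ECVF,modularity,HV2,0.094,0.094
ECVF,modularity,HV3,0.134,0.117
ECVF,modularity,HV4,0.082,0.062
ECVF,clustering,HV1,0.532,0.54
ECVF,clustering,HV2,0.463,0.523
ECVF,clustering,HV3,0.474,0.491
ECVF,clustering,HV4,0.515,0.545
ECVF,strength,HV1,184.885,198.415
ECVF,strength,HV2,162.356,185.485
ECVF,strength,HV3,158.943,171.443
ECVF,strength,HV4,168.561,195.199
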