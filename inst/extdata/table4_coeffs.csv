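response_code,predictor_code,coefficient
s410,e570,0.128
s410,b410,0.150
b134,e260,0.041
b134,e155,0.046
b144,e260,0.231
b152,e260,0.005
b152,s410,0.020
b740,e570,0.011
b740,e260,-0.040
b740,e155,-0.021
d240,d630,0.094
d455,e570,0.048
d630,b620,0.058
d630,e250,0.047
d630,e225,0.042
d770,s430,0.208
d770,e330,0.046
d770,e260,-0.052
d770,e225,0.067
d770,e155,0.078
d920,d630,0.235
d920,e260,-0.095
d920,e155,-0.197
d920,e110,0.045
e110,e155,0.141
e125,s410,0.064
e155,b730,0.021
e155,e260,0.014
e155,e110,0.012
e260,e570,0.027
e260,b460,0.029
e310,b740,0.014
e450,b620,0.016
e450,d630,0.021
e450,e225,0.240
e580,b460,0.073
e580,b410,0.206
e580,s410,0.010
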