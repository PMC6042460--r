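Category,s430,e330,b620,e250,d630,b730,b740,e570,e260,b460,e225,d570,b410,e155,e110,s410
s410,00000000.12800000.150000
b134,000000000.04100000.04600
b144,000000000.2310000000
b152,000000000.0050000000.020
b740,00000000.011-0.0400000-0.02100
d240,00000.09400000000000
d450,0000000000000000
d455,00000000.04800000000
d460,0000000000000000
d570,0000000000000000
d630,000.0580.0470000000.04200000
d760,0000000000000000
d770,0.2080.046000000-0.05200.067000.07800
d870,0000000000000000
d920,00000.235000-0.0950000-0.1970.0450
e110,00000000000000.14100
e125,0000000000000000.064
e155,000000.021000.014000000.0120
e260,00000000.02700.029000000
e310,0000000.014000000000
e355,0000000000000000
e450,000.01600.021000000.24000000
e580,0000000000.073000.206000.010
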