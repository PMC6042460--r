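code,out_degree
s410,4
b740,6
d920,6
e575,7
s430,3
b460,6
d770,6
e325,7
b415,6
d850,5
e580,6
b410,6
d640,5
e410,6
b455,5
d630,5
e250,6
b152,5
d620,5
e110,6
b130,5
d570,4
e570,5
b730,4
d455,4
e315,5
b530,4
d460,3
e225,5
b144,4
d450,3
e450,4
b134,4
d240,3
e320,4
b420,3
d230,3
e310,4
d430,2
e125,4
d870,1
e330,3
d760,0
e260,3
e155,3
e355,2
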