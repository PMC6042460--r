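response_code,predictor_code,coefficient
b130,d240,0.002
b130,d460,0.072
b130,d450,0.858
b134,b144,0.081
b134,d640,0.779
b144,b152,0.862
b144,d640,0.11
b152,d450,0.024
b152,b144,0.857
b415,d640,0.026
b415,b420,0.758
b420,d640,0.015
b420,b415,0.773
b530,e450,0.755
d240,d920,0.056
d240,d460,0.869
d430,d920,0.86
d450,b130,0.916
d450,b152,0.09
d450,d640,0.017
d460,d240,0.778
d460,b130,0.03
d770,d870,0.968
d870,d770,0.968
e450,b530,0.816
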