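Category,d770,d870,b530,e450,d920,d240,d460,b130,d450,b152,b144,d640,b415,b420
b130,000000.0020.07200.85800000
b134,00000000000.0810.77900
b144,0000000000.86200.1100
b152,000000000.02400.857000
b415,000000000000.02600.758
b420,000000000000.0150.7730
b530,0000.7550000000000
d240,00000.05600.8690000000
d430,00000.86000000000
d450,00000000.91600.0900.01700
d460,000000.77800.03000000
d770,00.968000000000000
d870,0.9680000000000000
e450,000.81600000000000
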