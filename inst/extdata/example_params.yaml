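# Reference example parameter set for the delayed diffusive logistic model
# with feedback control; domain (0, l*pi) = (0, 2*pi).
d1: 1.0
d2: 0.5
r: 0.6
K: 1.0
a1: 2.0
a2: 2.0
c: 1.0
b: 1.0
a: 1.0
l: 2.0
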