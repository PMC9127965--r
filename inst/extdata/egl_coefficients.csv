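name,value
a,6.3965167452414277705
b,0.3956414970297900124
c,0.2170821631949166608
d,0.0074888809560444795
e,0.0104337646062595234
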