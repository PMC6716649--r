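"age","weight"
25,0.0181203619444041
30,0.0374081406913163
35,0.0666071163007711
40,0.102289344279462
45,0.135486309023615
50,0.154780299597248
55,0.152507502272202
60,0.129605069099308
65,0.0949965912140965
70,0.0600550191177094
75,0.0327450646037686
80,0.0153991818560983
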