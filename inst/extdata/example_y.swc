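# Minimal Y-shaped example morphology (id type x y z radius parent)
1 1 0.0 0.0 0.0 1.0 -1
2 3 0.0 15.0 0.0 0.5 1
3 3 0.0 30.0 0.0 0.5 2
4 3 30.0 70.0 0.0 0.4 3
5 3 -30.0 70.0 0.0 0.4 3
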