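very	1.3
really	1.3
extremely	1.5
so	1.2
absolutely	1.4
slightly	0.7
somewhat	0.8
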