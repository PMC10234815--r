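X	2699520	154931043
Y	2649520	59034049
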