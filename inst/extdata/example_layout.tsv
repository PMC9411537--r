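name	length_bp
scaf1	600000
scaf2	600000
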