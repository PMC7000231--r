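pattern	low	high
pre[- ]?menopausal	0	50
early[- ]onset	0	45
\byoung\b	0	45
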