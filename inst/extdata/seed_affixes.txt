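# problem affixes, one per line, tokens whitespace-separated
TAMRA
TAMRA T
and
:
R :
F :
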