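"",normal,mild,moderate,severe
normal,39,4,2,0
mild,7,22,4,6
moderate,4,7,28,9
severe,1,2,7,35
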