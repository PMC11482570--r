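"",normal,mild,moderate,severe
normal,37,5,2,2
mild,5,20,6,7
moderate,5,8,24,9
severe,1,2,9,32
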