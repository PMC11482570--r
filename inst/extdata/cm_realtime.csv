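"",normal,mild,moderate,severe
normal,47,4,1,0
mild,3,29,2,1
moderate,2,2,34,5
severe,0,0,3,43
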