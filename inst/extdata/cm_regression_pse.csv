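pred,absent,mild,substantial
absent,2976,839,104
mild,784,778,455
substantial,97,248,862
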