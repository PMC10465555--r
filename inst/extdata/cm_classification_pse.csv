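pred,absent,mild,substantial
absent,2508,740,181
mild,1144,942,467
substantial,205,183,773
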