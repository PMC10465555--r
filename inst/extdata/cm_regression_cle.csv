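pred,absent,trace,mild,moderate,confluent,advanced
absent,1734,536,206,17,0,0
trace,696,635,682,142,2,0
mild,56,121,393,319,21,0
moderate,11,26,117,453,192,8
confluent,2,3,10,113,334,83
advanced,0,1,1,5,107,117
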