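pred,absent,trace,mild,moderate,confluent,advanced
absent,1621,530,259,21,0,0
trace,625,451,322,50,0,0
mild,230,294,664,288,4,0
moderate,22,42,142,514,141,7
confluent,0,3,15,153,322,42
advanced,1,2,7,23,189,159
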