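pred,absent,trace,mild,moderate,confluent,advanced
absent,637,126,35,2,0,0
trace,1495,751,380,23,1,0
mild,324,377,678,166,4,0
moderate,41,66,296,643,154,8
confluent,2,2,20,211,428,108
advanced,0,0,0,4,69,92
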