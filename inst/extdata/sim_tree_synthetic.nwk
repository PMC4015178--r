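((t1:0.4,t2:0.6):0.3,((t3:0.5,t4:0.7):0.2,(t5:0.3,(t6:0.4,t7:0.5):0.3):0.2):0.3);
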