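id,trom_t1,srom_c45_t1,srom_c56_t1,srom_c67_t1,trom_t2,srom_c45_t2,srom_c56_t2,srom_c67_t2,seq_t1,seq_t2
E1,11.2,7.4,1.0,2.8,12.4,6.2,3.3,2.8,-,-
E2,10.6,4.2,4.4,2.0,10.3,4.1,5.4,0.7,-,-
E3,8.2,2.2,2.5,3.5,12.6,4.0,4.2,4.3,-,-
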