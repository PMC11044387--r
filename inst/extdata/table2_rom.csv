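id,trom_t1,srom_c45_t1,srom_c56_t1,srom_c67_t1,trom_t2,srom_c45_t2,srom_c56_t2,srom_c67_t2
1,23.2,14.7,0.2,8.3,15.3,3.6,5.0,6.8
2,55.8,23.9,20.9,11.0,53.5,14.5,17.5,21.6
3,13.1,6.5,2.7,4.0,10.8,4.4,2.9,3.5
4,25.2,4.9,0.2,20.2,8.1,5.9,1.0,1.1
5,21.1,13.1,4.7,3.3,19.4,12.5,3.5,3.4
6,24.9,9.7,8.2,7.0,22.1,11.1,6.4,4.5
7,15.5,10.2,4.7,0.6,23.9,14.5,5.7,3.8
8,16.4,9.2,7.3,0.2,13.9,6.5,4.8,2.6
9,27.4,9.1,14.7,3.7,22.4,11.5,8.6,2.3
10,35.5,10.2,15.3,10.1,33.6,8.9,15.2,9.5
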