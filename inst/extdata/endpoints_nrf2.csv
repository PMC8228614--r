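abbrev,raw_value,transformed_value,role
DEHP,0.6449,0.6449,train
DEP,1.2220,1.2220,test
DMP,1.1534,1.1534,train
DMEP,1.1691,1.1691,train
DHXP,0.6882,0.6882,test
DNOP,0.7129,0.7129,train
DBP,0.7363,0.7363,train
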