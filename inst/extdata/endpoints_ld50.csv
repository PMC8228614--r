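abbrev,raw_value,transformed_value,role
DMP,6800,3.8325,train
DEP,8600,3.9345,test
DBP,7499,3.875,train
DIBP,15000,4.1761,train
DHXP,29600,4.4713,train
DNOP,47000,4.6721,train
DIOP,22000,4.3424,train
DEHP,30000,4.4771,train
DNP,21500,4.3324,train
DIDP,64000,4.8062,test
nDNOP,45200,4.6551,train
DAP,656,2.8169,train
DMEP,2750,3.4393,test
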