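abbrev,raw_value,transformed_value,role
DEHP,1160,3.0645,train
DNP,1513,3.18,train
DIDP,1722,3.236,train
DMEP,975.1,2.989,train
DHXP,1227,3.0888,test
DNOP,1678,3.225,train
DPHP,954.9,2.98,test
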