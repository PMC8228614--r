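abbrev,model,exp,pred,res
DMP,CoMFA,3.8325,3.791,0.0415
DEP,CoMFA,3.9345,3.89,0.0445
DBP,CoMFA,3.875,3.955,-0.08
DIBP,CoMFA,4.1761,4.241,-0.0649
DHXP,CoMFA,4.4713,4.417,0.0543
DNOP,CoMFA,4.6721,4.647,0.0251
DIOP,CoMFA,4.3424,4.374,-0.0316
DEHP,CoMFA,4.4771,4.475,0.0021
DNP,CoMFA,4.3324,4.458,-0.1256
DIDP,CoMFA,4.8062,4.759,0.0472
nDNOP,CoMFA,4.6551,4.604,0.0511
DAP,CoMFA,2.8169,2.821,-0.0041
DMEP,CoMFA,3.4393,3.436,0.0033
DMP,CoMSIA,3.8325,3.829,0.0035
DEP,CoMSIA,3.9345,3.942,-0.0075
DBP,CoMSIA,3.875,3.896,-0.021
DIBP,CoMSIA,4.1761,4.175,0.0011
DHXP,CoMSIA,4.4713,4.45,0.0213
DNOP,CoMSIA,4.6721,4.684,-0.0119
DIOP,CoMSIA,4.3424,4.339,0.0034
DEHP,CoMSIA,4.4771,4.477,0.0001
DNP,CoMSIA,4.3324,4.332,0.0004
DIDP,CoMSIA,4.8062,4.804,0.0022
nDNOP,CoMSIA,4.6551,4.647,0.0081
DAP,CoMSIA,2.8169,2.815,0.0019
DMEP,CoMSIA,3.4393,3.419,0.0203
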