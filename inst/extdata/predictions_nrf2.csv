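abbrev,model,exp,pred,res
DEHP,CoMSIA,0.6449,0.646,-0.0011
DEP,CoMSIA,1.2220,1.140,0.082
DMP,CoMSIA,1.1534,1.151,0.0024
DMEP,CoMSIA,1.1691,1.170,-0.0009
DHXP,CoMSIA,0.6882,0.673,0.0152
DNOP,CoMSIA,0.7129,0.720,-0.0071
DBP,CoMSIA,0.7363,0.746,-0.0097
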