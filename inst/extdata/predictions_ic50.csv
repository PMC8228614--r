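abbrev,model,exp,pred,res
DEHP,CoMFA,3.0645,3.053,0.0115
DNP,CoMFA,3.18,3.206,-0.026
DIDP,CoMFA,3.236,3.232,0.004
DMEP,CoMFA,2.989,2.984,0.005
DHXP,CoMFA,3.0888,3.091,-0.0022
DNOP,CoMFA,3.225,3.206,0.019
DPHP,CoMFA,2.98,2.992,-0.012
DEHP,CoMSIA,3.0645,3.069,-0.0045
DNP,CoMSIA,3.18,3.2,0.025
DIDP,CoMSIA,3.236,3.094,-0.0052
DMEP,CoMSIA,2.989,2.992,-0.003
DHXP,CoMSIA,3.0888,2.972,0.008
DNOP,CoMSIA,3.225,3.233,0.003
DPHP,CoMSIA,2.98,3.203,-0.023
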