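name,network,x,y,z,radius
VLPFC_R,FPN,40,48,-5,10
VLPFC_L,FPN,-40,48,-5,10
DLPFC_R,FPN,43,22,34,10
DLPFC_L,FPN,-43,22,34,10
SPC_R,FPN,37,-61,48,10
SPC_L,FPN,-32,-61,48,10
dACC,FPN,-2,35,43,10
IPC_R,DMN,55,-57,25,10
IPC_L,DMN,-55,-57,25,10
vmPFC,DMN,0,57,-10,10
PCC,DMN,0,-51,31,10
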