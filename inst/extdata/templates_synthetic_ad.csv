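channel,A,B,C,D
Fp1,0.179646,0.359291,-0.184696,-0.043395
Fp2,0.359291,0.179646,-0.184696,-0.043395
F7,-0.059882,0.359291,-0.182213,-0.065971
F3,0.044911,0.284439,-0.179214,0.209594
Fz,0.179646,0.179646,-0.178329,0.439352
F4,0.284439,0.044911,-0.179214,0.209594
F8,0.359291,-0.059882,-0.182213,-0.065971
T3,-0.269468,0.269468,-0.168548,-0.169776
C3,-0.134734,0.134734,-0.060161,0.188435
Cz,0,0,0.060216,0.586275
C4,0.134734,-0.134734,-0.060161,0.188435
T4,0.269468,-0.269468,-0.168548,-0.169776
T5,-0.359291,0.059882,-0.031239,-0.194353
P3,-0.284439,-0.044911,0.28868,-0.154885
Pz,-0.179646,-0.179646,0.629216,-0.134439
P4,-0.044911,-0.284439,0.28868,-0.154885
T6,0.059882,-0.359291,-0.031239,-0.194353
O1,-0.359291,-0.179646,0.261838,-0.215243
O2,-0.179646,-0.359291,0.261838,-0.215243
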