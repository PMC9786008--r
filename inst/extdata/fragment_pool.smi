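CC
CCC
CCCC
CCO
CCN
CO
CN
C(C)C
CCOC
CCNC
c1ccccc1
Cc1ccccc1
CCc1ccccc1
c1ccncc1
Cc1ccncc1
c1ccco1
c1cccs1
C1CCCCC1
C1CCCC1
C1CCNCC1
C1CCOCC1
CC(C)C
CCCO
CCCN
COC
CNC
CC(C)O
CC(C)N
c1ccc2ccccc2c1
C1CC1
C1CCC1
CCCCC
OCCO
NCCN
CCOCC
CCNCC
c1cnccn1
Cc1cccnc1
CC(C)(C)C
CCCCO
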