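experiment,treatment,region,mean,se
actin_ca,0h Control,outer_periclinal,43,7
actin_ca,0h Control,anticlinal,0,0
actin_ca,0h Control,inner_periclinal,33,6
actin_ca,15h Control,outer_periclinal,385,17
actin_ca,15h Control,anticlinal,25,5
actin_ca,15h Control,inner_periclinal,13,4
actin_ca,15h Latrunculin B (100 nM),outer_periclinal,184,18
actin_ca,15h Latrunculin B (100 nM),anticlinal,121,13
actin_ca,15h Latrunculin B (100 nM),inner_periclinal,180,15
actin_ca,15h Jasplakinolide (100 nM),outer_periclinal,184,25
actin_ca,15h Jasplakinolide (100 nM),anticlinal,101,10
actin_ca,15h Jasplakinolide (100 nM),inner_periclinal,176,25
actin_ca,15h Nifedipine (100 uM),outer_periclinal,165,11
actin_ca,15h Nifedipine (100 uM),anticlinal,111,7
actin_ca,15h Nifedipine (100 uM),inner_periclinal,142,8
exo_endo,9h Control,outer_periclinal,513,26
exo_endo,9h Control,anticlinal,35,7
exo_endo,9h Control,inner_periclinal,0,0
exo_endo,9h+6h Control,outer_periclinal,364,13
exo_endo,9h+6h Control,anticlinal,20,4
exo_endo,9h+6h Control,inner_periclinal,19,7
exo_endo,9h+6h BDM (50 mM),outer_periclinal,159,11
exo_endo,9h+6h BDM (50 mM),anticlinal,102,15
exo_endo,9h+6h BDM (50 mM),inner_periclinal,174,12
exo_endo,9h+6h Wortmannin (33 uM),outer_periclinal,24,7
exo_endo,9h+6h Wortmannin (33 uM),anticlinal,0,0
exo_endo,9h+6h Wortmannin (33 uM),inner_periclinal,32,8
dynamin,9h Control,outer_periclinal,520,22
dynamin,9h Control,anticlinal,24,7
dynamin,9h Control,inner_periclinal,22,9
dynamin,9h+6h Control,outer_periclinal,368,13
dynamin,9h+6h Control,anticlinal,28,7
dynamin,9h+6h Control,inner_periclinal,23,6
dynamin,9h+6h Dynasore (100 uM),outer_periclinal,0,0
dynamin,9h+6h Dynasore (100 uM),anticlinal,0,0
dynamin,9h+6h Dynasore (100 uM),inner_periclinal,39,7
dynamin,9h+6h Dyngo 4a (20 uM),outer_periclinal,36,7
dynamin,9h+6h Dyngo 4a (20 uM),anticlinal,0,0
dynamin,9h+6h Dyngo 4a (20 uM),inner_periclinal,27,6
dynamin,9h+6h Dyngo Phi (20 uM),outer_periclinal,381,13
dynamin,9h+6h Dyngo Phi (20 uM),anticlinal,14,5
dynamin,9h+6h Dyngo Phi (20 uM),inner_periclinal,25,8
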