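experiment,treatment,mean,se
actin_ca,0h Control,76,10
actin_ca,15h Control,424,19
actin_ca,15h Latrunculin B (100 nM),505,27
actin_ca,15h Jasplakinolide (100 nM),461,37
actin_ca,15h Nifedipine (100 uM),418,15
exo_endo,9h Control,548,27
exo_endo,9h+6h Control,403,15
exo_endo,9h+6h BDM (50 mM),435,22
exo_endo,9h+6h Wortmannin (33 uM),56,10
dynamin,9h Control,566,25
dynamin,9h+6h Control,429,22
dynamin,9h+6h Dynasore (100 uM),39,7
dynamin,9h+6h Dyngo 4a (20 uM),63,9
dynamin,9h+6h Dyngo Phi (20 uM),420,16
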