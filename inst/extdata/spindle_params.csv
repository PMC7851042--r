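fiber,K_SR,K_PR,M,beta0,beta1,beta2,Gamma1,Gamma2,L0_SR,L0_PR,L_N_SR,L_N_PR,tau,freq,p,C_L,C_S,a,R,G_pri,G_sec,X,L_sec
bag1,10.4649,0.15,0.0002,0.0605,0.2592,0,0.0289,0,0.04,0.76,0.0423,0,0.149,60,2,1,0.42,0.3,0.46,20000,0,0,0.04
bag2,10.4649,0.15,0.0002,0.0822,0,-0.046,0,0.0636,0.04,0.76,0.0423,0.89,0.205,60,2,1,0.42,0.3,0.46,10000,7250,0.7,0.04
chain,10.4649,0.15,0.0002,0.0822,0,-0.069,0,0.0954,0.04,0.76,0.0423,0.89,0.0001,90,2,1,0.42,0.3,0.46,10000,7250,0.7,0.04
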