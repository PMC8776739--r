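species,treatment,interval,mean_inhibition,sd,n
SM,Control,0-4,0,0.004,3
SM,Control,4-7,0,0.018,3
SM,Control,7-10,0,0.048,3
SM,Ag,0-4,1.29,0.057,3
SM,Ag,4-7,1.1,0.048,3
SM,Ag,7-10,1.1,0.29,3
SM,Cd,0-4,0.29,0.043,3
SM,Cd,4-7,0.62,0.066,3
SM,Cd,7-10,0.6,0.039,3
SM,Cu,0-4,0.6,0.019,3
SM,Cu,4-7,0.61,0.048,3
SM,Cu,7-10,1.3,0.11,3
TB,Control,0-4,0,0.012,3
TB,Control,4-7,0,0.053,3
TB,Control,7-10,0,0.11,3
TB,Ag,0-4,0.1,0.15,3
TB,Ag,4-7,0.16,0.054,3
TB,Ag,7-10,0.025,0.025,3
TB,Cd,0-4,0.78,0.23,3
TB,Cd,4-7,0.98,0.44,3
TB,Cd,7-10,0.89,0.48,3
TB,Cu,0-4,0.1,0.068,3
TB,Cu,4-7,0.24,0.03,3
TB,Cu,7-10,1.2,0.39,3
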