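# Measured, substrate-specific model inputs for maize in two substrates.
parameter,loam,sand,unit
theta,0.22,0.18,cm3 cm-3
a_primary,0.05,0.05,cm
a_tip,0.0095,0.0445,cm
RL_tot,10917,3388,cm
RWU21,73.3,68.6,cm3 d-1
Jw_daily,5.38e-7,1.04e-6,cm s-1
c_tot_ini_Ca,1.27e-4,7.47e-6,mol cm-3
c_tot_ini_S,1.37e-5,5.65e-6,mol cm-3
c_tot_ini_P,2.99e-6,4.07e-6,mol cm-3
l_rh,230,244,um
N_hairs,165,164,cm-1
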