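# Substrate-independent constants: diffusion impedance, gypsum precipitation
# kinetics and root-hair geometry. Values are stored in the units they are
# usually reported in; the loader converts to the cm/s/mol system.
parameter,value,unit
f_impedance,0.3,-
k_precip,2,l mol-1 min-1
Ksp_CaSO4,2.4e-5,mol2 l-2
a_h,4e-4,cm
L_char,1,cm
hair_lifetime,2,d
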