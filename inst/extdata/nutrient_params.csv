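# Per-nutrient transport and uptake constants (literature values).
# D: liquid diffusion coefficient [cm2 s-1]; Fm: maximum root uptake rate
# [mol cm-2 s-1]; Km: half-saturation concentration [mol cm-3]; b_*: soil
# buffer power (solid-to-solution partition coefficient, dimensionless) per
# substrate. Root hairs use Fmh = Fm (or a scenario-level multiple) and
# Kmh = Km.
element,D_cm2_s,Fm_mol_cm2_s,Km_mol_cm3,b_loam,b_sand
Ca,7.92e-06,1.00e-12,4.00e-06,2,0.3
S,6.00e-06,3.00e-13,1.00e-08,2,0.35
P,6.90e-06,3.26e-12,5.80e-09,239,41.3
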