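# Poly-DL-alanine reference rate constants and temperature parameters, version 1
# (set "bai1993-spreadsheet"). Rate constants are log10 values at the reference
# temperature T_ref; units are M^-1 min^-1 for the acid- and base-catalysed terms
# and min^-1 for the water term. Activation energies in cal/mol, applied as
# k(T) = k(T_ref) * exp(-Ea/R * (1/T - 1/T_ref)) with R = 1.987 cal/(mol K).
# The base-term activation energy is the apparent value at constant pD (it folds
# in the temperature dependence of the D2O ion product), so pKD is used untouched
# at all temperatures. pKa values are side-chain ionisation constants on the pD
# scale used for protonated/deprotonated factor mixing.
name	value
log10_kA_ref	1.62
log10_kB_ref	10.18
log10_kW_ref	-1.5
Ea_acid	14000
Ea_base	17000
Ea_water	19000
T_ref	293.15
pKD	15.05
pKa_Asp	4.48
pKa_Glu	4.93
pKa_His	7.42
pKa_Cterm	4.00
valid_pD_min	1.0
valid_pD_max	13.0
valid_T_min	263.15
valid_T_max	323.15
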