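res_name	atom_name	charge_e	sigma_nm	epsilon_kjmol
TPA	X1	0.30	0.33	0.50
TPA	X2	0.10	0.32	0.60
TPB	X1	-0.20	0.35	0.70
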