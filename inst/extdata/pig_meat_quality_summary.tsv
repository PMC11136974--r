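item	mean_nc	sd_nc	n_nc	mean_hc	sd_hc	n_hc	printed_significance
initial_bw_kg	107.5	4.504	8	108.75	5.701	8	P>0.05
final_bw_kg	131.875	2.588	8	141.000	4.986	8	P<0.01
adg_kg	0.772	0.044	8	0.967	0.033	8	P<0.01
backfat_thickness_cm	2.783	0.194	8	1.933	0.339	8	P<0.01
ph_0h	5.811	0.237	8	5.881	0.344	8	P>0.05
ph_24h	5.476	0.381	8	5.296	0.636	8	P>0.05
electrical_conductivity	1.460	0.342	8	1.85	0.469	8	P>0.05
water_holding_capacity_ms	1.460	0.312	8	1.92	0.437	8	P>0.05
shear_force_n	2.800	0.699	8	3.282	0.757	8	P>0.05
meat_color	72.215	7.544	8	83.353	3.021	8	P<0.05
intramuscular_tg_nmol_mg	56.965	5.783	8	71.062	5.771	8	P<0.05
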