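# Published free energy decomposition of crizotinib binding to ROS1
# tyrosine kinase (kcal/mol at 310 K; S* in A^2, I* in A, K_bind in A^3).
# Component rows feed the Woo-Roux assembly; result rows (k_bind,
# dg_bind_us, ddg_bind_us, dg_off, dg_bind_meta, sep_pmf) are the printed
# values used for comparison in the reproduction mode.
component	wt	g2032r
dgc_site	0.073	0.323
dgc_bulk	1.639	1.772
dgo_alpha	0.410	0.617
dgo_beta	0.892	0.520
dgo_gamma	0.210	0.389
dgo_bulk	7.135	7.230
dgt_theta	0.355	0.214
dgt_Theta	0.162	0.165
sep_pmf	-24.96	-18.32
s_star	9.834	8.950
i_star	1.98e17	4.44e12
k_bind	3.85e13	6.64e8
dg_bind_us	-14.70	-7.95
ddg_bind_us	-6.75	-6.75
dg_off	12.10	5.53
dg_bind_meta	-10.14	-5.91
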