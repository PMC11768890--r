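name	compound_class	mass_conc_ug_ml	molar_mass_g_mol	expected_um
madecassoside	TT	1.7945	975.12	1.84
asiaticoside	TT	0.7376	959.12	0.769
madecassic acid	TT	0.0377	504.70	0.073
asiatic acid	TT	0.021	488.70	0.043
chlorogenic acid	CQA	0.3749	354.31	1.06
neo-chlorogenic acid	CQA	0.1695	354.31	0.478
crypto-chlorogenic acid	CQA	0.1492	354.31	0.421
3,4-dicaffeoylquinic acid	CQA	0.1146	516.45	0.221
3,5-dicaffeoylquinic acid	CQA	0.0884	516.45	0.171
4,5-dicaffeoylquinic acid	CQA	0.0975	516.45	0.189
1,3-dicaffeoylquinic acid	CQA	0.1291	516.45	0.250
1,5-dicaffeoylquinic acid	CQA	0.1946	516.45	0.377
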