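label,method_class,qm_size,ts1_minus_ts2_kcal
cc_372,coupled_cluster,372,5.21
cc_238,coupled_cluster,238,4.13
cc_101,coupled_cluster,101,1.66
dft_e_372,embedded_dft,372,3.65
dft_s_238,embedded_dft,238,3.15
dft_101,hybrid_dft,101,0.62
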