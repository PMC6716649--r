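"analysis","strategy","inc_qalys_vs_none","inc_cost_vs_none_gbp"
"base_case","MSI_METH",34.5,545000
"base_case","DIRECT",35.1,769000
"base_case","IHC_METH",37.9,538000
"base_case","MSI",38.3,771000
"base_case","IHC",40.2,826000
"psa","MSI_METH",37.6,573000
"psa","DIRECT",38,767000
"psa","IHC_METH",41.4,554000
"psa","MSI",42.7,855000
"psa","IHC",45.1,923000
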