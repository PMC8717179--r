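model,b_fibrillar,fibrillar_lower,fibrillar_upper,b_nonfibrillar,nonfibrillar_lower,nonfibrillar_upper
fibrillar x nonfibrillar x heterogeneity,3.521,2.954,4.041,0.259,0.178,0.341
fibrillar x nonfibrillar x heterogeneity x age,2.810,2.620,3.032,0.146,0.103,0.193
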