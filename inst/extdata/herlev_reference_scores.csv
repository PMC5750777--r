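scenario,approach,k,category,precision,recall,f1,kappa
by_k,all_features,2,overall,0.67,0.74,0.70,0.66
by_k,all_features,3,overall,0.68,0.69,0.68,0.64
by_k,all_features,4,overall,0.74,0.74,0.74,0.70
by_k,all_features,5,overall,0.76,0.76,0.76,0.72
by_k,all_features,6,overall,0.73,0.73,0.73,0.68
by_k,all_features,7,overall,0.69,0.70,0.69,0.64
by_k,p_fuzzy,2,overall,0.73,0.80,0.76,0.72
by_k,p_fuzzy,3,overall,0.76,0.77,0.76,0.72
by_k,p_fuzzy,4,overall,0.83,0.84,0.83,0.81
by_k,p_fuzzy,5,overall,0.80,0.81,0.80,0.76
by_k,p_fuzzy,6,overall,0.74,0.76,0.75,0.70
by_k,p_fuzzy,7,overall,0.71,0.72,0.71,0.67
by_k,q_fuzzy,2,overall,0.73,0.79,0.76,0.71
by_k,q_fuzzy,3,overall,0.77,0.77,0.77,0.73
by_k,q_fuzzy,4,overall,0.85,0.86,0.85,0.83
by_k,q_fuzzy,5,overall,0.80,0.81,0.80,0.76
by_k,q_fuzzy,6,overall,0.74,0.75,0.74,0.69
by_k,q_fuzzy,7,overall,0.73,0.74,0.73,0.69
by_class,all_features,5,normal_superficial,0.83,0.86,0.84,NA
by_class,all_features,5,normal_intermediate,0.82,0.74,0.78,NA
by_class,all_features,5,normal_columnar,0.63,0.67,0.65,NA
by_class,all_features,5,carcinoma_in_situ,0.74,0.83,0.78,NA
by_class,all_features,5,light_dysplastic,0.83,0.78,0.81,NA
by_class,all_features,5,moderate_dysplastic,0.69,0.85,0.76,NA
by_class,all_features,5,severe_dysplastic,0.79,0.62,0.70,NA
by_class,p_fuzzy,4,normal_superficial,0.95,0.91,0.93,NA
by_class,p_fuzzy,4,normal_intermediate,0.89,0.84,0.86,NA
by_class,p_fuzzy,4,normal_columnar,0.65,0.72,0.68,NA
by_class,p_fuzzy,4,carcinoma_in_situ,0.81,0.87,0.84,NA
by_class,p_fuzzy,4,light_dysplastic,0.88,0.94,0.91,NA
by_class,p_fuzzy,4,moderate_dysplastic,0.83,0.96,0.89,NA
by_class,p_fuzzy,4,severe_dysplastic,0.86,0.65,0.74,NA
by_class,q_fuzzy,4,normal_superficial,0.95,0.95,0.95,NA
by_class,q_fuzzy,4,normal_intermediate,0.89,0.89,0.89,NA
by_class,q_fuzzy,4,normal_columnar,0.61,0.74,0.67,NA
by_class,q_fuzzy,4,carcinoma_in_situ,0.84,0.90,0.87,NA
by_class,q_fuzzy,4,light_dysplastic,0.89,0.97,0.93,NA
by_class,q_fuzzy,4,moderate_dysplastic,0.89,0.96,0.93,NA
by_class,q_fuzzy,4,severe_dysplastic,0.88,0.61,0.72,NA
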