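variable,mean_nontree,sd_nontree,n_nontree,mean_tree,sd_tree,n_tree,F_printed,p_adj_printed,rounding_robust
tree_dbh_mean,0.009,0.007,5,0.060,0.068,4,2.92,0.394,FALSE
tree_height_mean,0.009,0.012,5,0.080,0.070,4,5.05,0.250,FALSE
dead_tree_density,0.001,0.001,5,0.001,0.002,4,0.61,0.918,FALSE
large_tree_density,0.038,0.036,5,0.522,0.281,4,15.07,0.042,TRUE
softwood_large_density,0.075,0.074,5,0.272,0.169,4,5.59,0.250,TRUE
development_stage,0.001,0.002,5,0.124,0.097,4,8.30,0.142,TRUE
wood_density_mean,0.048,0.090,5,0.017,0.012,4,0.47,0.918,FALSE
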