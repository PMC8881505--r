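species,abbrev,n_records,training_gain,auc_test,roosting,forager_class
Barbastella barbastellus,Bbar,16,1.92,0.975,tree,within-forest
Myotis bechsteinii,Mbec,49,1.68,0.922,tree,within-forest
Myotis emarginatus,Mema,98,0.52,0.749,non-tree,within-forest
Myotis escalerai,Mes,115,0.49,0.710,non-tree,within-forest
Nyctalus lasiopterus,Nlas,48,1.47,0.913,tree,open-space
Nyctalus leisleri,Nleis,48,1.48,0.938,tree,open-space
Plecotus austriacus,Paus,123,1.00,0.855,non-tree,within-forest
Rhinolophus euryale,Reur,173,0.18,0.629,non-tree,within-forest
Rhinolophus hipposideros,Rhip,322,0.16,0.626,non-tree,within-forest
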