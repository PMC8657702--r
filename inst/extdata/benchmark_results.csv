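compound_descriptor,protein_descriptor,regime,variant,mcc,bedroc
cddd,unirep,random,full,0.645,0.979
cddd,seqvec,random,full,0.575,0.967
cddd,esm,random,full,0.609,0.974
molbert,unirep,random,full,0.654,0.980
molbert,seqvec,random,full,0.607,0.973
molbert,esm,random,full,0.630,0.977
handcrafted,handcrafted,random,full,0.337,0.819
cddd,unirep,lcco,full,0.490,0.941
cddd,seqvec,lcco,full,0.475,0.930
cddd,esm,lcco,full,0.484,0.930
molbert,unirep,lcco,full,0.505,0.943
molbert,seqvec,lcco,full,0.487,0.938
molbert,esm,lcco,full,0.499,0.937
handcrafted,handcrafted,lcco,full,0.276,0.753
cddd,unirep,lpo,full,0.307,0.847
cddd,seqvec,lpo,full,0.322,0.851
cddd,esm,lpo,full,0.297,0.834
molbert,unirep,lpo,full,0.312,0.847
molbert,seqvec,lpo,full,0.311,0.842
molbert,esm,lpo,full,0.294,0.832
handcrafted,handcrafted,lpo,full,0.132,0.655
cddd,unirep,random,no_interaction,0.565,NA
cddd,seqvec,random,no_interaction,0.548,NA
cddd,esm,random,no_interaction,0.557,NA
molbert,unirep,random,no_interaction,0.574,NA
molbert,seqvec,random,no_interaction,0.558,NA
molbert,esm,random,no_interaction,0.567,NA
cddd,unirep,lcco,no_interaction,0.424,NA
cddd,seqvec,lcco,no_interaction,0.411,NA
cddd,esm,lcco,no_interaction,0.416,NA
molbert,unirep,lcco,no_interaction,0.439,NA
molbert,seqvec,lcco,no_interaction,0.430,NA
molbert,esm,lcco,no_interaction,0.434,NA
cddd,unirep,lpo,no_interaction,0.281,NA
cddd,seqvec,lpo,no_interaction,0.287,NA
cddd,esm,lpo,no_interaction,0.287,NA
molbert,unirep,lpo,no_interaction,0.283,NA
molbert,seqvec,lpo,no_interaction,0.290,NA
molbert,esm,lpo,no_interaction,0.292,NA
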