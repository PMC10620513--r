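parent_name,region_name,acronym,ratio_adlib_chamber_pct,ratio_adlib_hand_pct,ratio_sd_chamber_pct,ratio_sd_hand_pct,p_condition,p_method,p_interaction
Olfactory areas,Other olfactory areas,Other OLF,3.820,4.531,3.680,4.121,0.0550,0.0049,0.2572
Cortical subplate,Claustrum,CLA,2.883,7.357,4.020,4.724,0.3987,0.0309,0.0761
Cortical subplate,Basolateral amygdalar nucleus anterior part,BLAa,16.296,15.120,15.423,11.745,0.0385,0.0256,0.1481
Striatum,Caudoputamen,CP,27.470,28.719,31.707,42.050,0.0007,0.0033,0.0079
Striatum,Nucleus accumbens,ACB,8.389,9.777,5.885,7.394,0.0012,0.0080,0.8488
Striatum,Septohippocampal nucleus,SH,0.064,0.063,0.000,0.013,0.0081,0.6494,0.5938
Striatum,Other striatum,Other STR,7.498,8.414,10.562,7.317,0.1565,0.1081,0.0211
Pallidum,Globus pallidus external segment,GPe,9.399,8.969,11.484,7.482,0.6855,0.0320,0.0599
Pallidum,Magnocellular nucleus,MA,2.856,1.520,3.176,2.400,0.0988,0.0197,0.3744
Thalamus,Reticular nucleus of the thalamus,RT,2.693,1.693,1.457,1.219,0.0298,0.0747,0.2142
Thalamus,Epithalamus,EPI,1.576,0.941,1.051,3.171,0.0204,0.0315,0.0038
Hypothalamus,Anteroventral preoptic nucleus,AVP,0.195,0.273,0.781,0.152,0.0918,0.0592,0.0283
Hypothalamus,Medial preoptic area,MPO,3.051,3.803,2.739,4.916,0.4270,0.0321,0.1916
Hypothalamus,Vascular organ of the lamina terminalis,OV,0.016,0.000,0.100,0.000,0.0126,0.0041,0.0126
Hypothalamus,Periventricular hypothalamic nucleus preoptic part,PVpo,1.421,1.791,0.630,0.879,0.0069,0.1355,0.7346
Hypothalamus,Ventromedial preoptic nucleus,VMPO,0.687,0.579,0.037,0.382,0.0073,0.2315,0.0544
Hypothalamus,Anterior hypothalamic nucleus,AHN,4.714,5.904,7.658,4.289,0.1290,0.0353,0.0028
Hypothalamus,Lateral hypothalamic area,LHA,9.209,9.078,10.692,10.790,0.0218,0.9711,0.8070
Hypothalamus,Preparasubthalamic nucleus,PST,0.460,0.000,0.151,0.000,0.0910,0.0118,0.0910
Hypothalamus,Tuberal nucleus,TU,3.781,3.291,3.749,2.130,0.1289,0.0279,0.1453
Midbrain,Superior colliculus optic layer,SCop,5.812,4.009,3.863,5.086,0.4099,0.5732,0.0332
Midbrain,Inferior colliculus dorsal nucleus,ICd,2.570,4.477,2.256,5.311,0.6170,0.0067,0.2978
Midbrain,Parabigeminal nucleus,PBG,0.000,0.000,0.044,0.012,0.0272,0.1277,0.1277
Midbrain,Ventral tegmental area,VTA,0.371,0.434,0.749,0.772,0.0461,0.7514,0.8823
Midbrain,Superior colliculus motor related intermediate white layer,SCiw,8.014,5.930,8.213,5.865,0.9097,0.0163,0.8245
Midbrain,Superior colliculus motor related intermediate gray layer,SCig,10.550,7.829,8.515,7.814,0.1142,0.0282,0.1181
Midbrain,Medial terminal nucleus of the accessory optic tract,MT,0.039,0.097,0.157,0.000,0.6909,0.1292,0.0144
Midbrain,Interpeduncular nucleus,IPN,0.424,0.609,0.249,1.187,0.1336,0.0064,0.0247
Midbrain,Rostral linear nucleus raphe,RL,0.312,0.182,0.156,0.101,0.0297,0.0628,0.3605
Pons,Pontine gray,PG,35.926,27.559,23.416,35.250,0.5418,0.6569,0.0492
Pons,Pontine reticular nucleus,PRNr,4.051,3.631,6.604,2.657,0.3591,0.0458,0.0819
Pons,Other pons,Other pons,16.009,24.533,17.390,25.570,0.5952,0.0164,0.9386
Medulla,Facial motor nucleus,VII,6.44,6.08,4.48,1.40,0.0410,0.1988,0.2892
Medulla,Magnocellular reticular nucleus,MARN,1.61,2.10,2.27,4.96,0.0255,0.0349,0.0962
Medulla,Vestibular nuclei,VNC,12.17,8.52,5.88,7.90,0.0358,0.5045,0.0634
Medulla,Nucleus raphe magnus,RM,1.19,0.74,1.59,0.10,0.5941,0.0091,0.0645
Cerebellum,Lobule III,CENT3,15.618,9.265,20.029,8.415,0.5045,0.0209,0.3401
Fiber tracts,Oculomotor nerve,IIIn,0.174,0.034,0.000,0.000,0.0164,0.0548,0.0548
Fiber tracts,Brachium of the inferior colliculus,bic,0.528,0.911,1.898,0.643,0.1191,0.1930,0.0424
Fiber tracts,Medial lemniscus,ml,10.581,5.553,5.084,5.453,0.0242,0.0424,0.0271
Fiber tracts,Genu of corpus callosum,ccg,1.023,0.525,0.202,0.364,0.0252,0.2982,0.0792
Fiber tracts,Corticospinal tract,cst,0.000,1.652,0.000,0.925,0.4308,0.0361,0.4308
Fiber tracts,Internal capsule,int,4.575,2.929,4.141,2.850,0.6170,0.0364,0.7275
Fiber tracts,Rubrospinal tract,rust,1.913,1.037,1.299,0.943,0.0407,0.0066,0.0942
Fiber tracts,Columns of the fornix,fx,2.469,1.217,1.190,0.663,0.0000,0.0000,0.0000
Fiber tracts,Mammillary peduncle,mp,0.053,0.211,0.425,0.065,0.1547,0.1906,0.0158
Ventricular systems,Lateral recess,V4r,7.836,9.559,1.793,15.837,0.9674,0.0436,0.0852
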