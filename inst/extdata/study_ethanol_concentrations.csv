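matrix,subject,cycle,region,timepoint,time_min,conc_gL
serum,V1,NA,NA,T1,0,0.26
serum,V2,NA,NA,T1,0,1.19
serum,V3,NA,NA,T1,0,0.54
brain,V1,1,occipital_cortex,NA,15,0.62
brain,V2,1,occipital_cortex,NA,15,0.60
brain,V3,1,occipital_cortex,NA,15,0.56
brain,V1,1,cerebellum,NA,25,0.62
brain,V2,1,cerebellum,NA,25,0.58
brain,V3,1,cerebellum,NA,25,0.50
serum,V1,NA,NA,T2,40,1.03
serum,V2,NA,NA,T2,40,1.08
serum,V3,NA,NA,T2,40,0.80
brain,V1,1,frontal_cortex,NA,45,0.68
brain,V2,1,frontal_cortex,NA,45,0.61
brain,V3,1,frontal_cortex,NA,45,0.62
brain,V1,1,putamen,NA,55,0.49
brain,V2,1,putamen,NA,55,0.51
brain,V3,1,putamen,NA,55,0.43
serum,V1,NA,NA,T3,70,1.14
serum,V2,NA,NA,T3,70,1.12
serum,V3,NA,NA,T3,70,0.87
brain,V1,2,occipital_cortex,NA,105,0.47
brain,V2,2,occipital_cortex,NA,105,0.42
brain,V3,2,occipital_cortex,NA,105,0.59
brain,V1,2,cerebellum,NA,115,0.39
brain,V2,2,cerebellum,NA,115,0.38
brain,V3,2,cerebellum,NA,115,0.42
serum,V1,NA,NA,T4,130,0.98
serum,V2,NA,NA,T4,130,0.98
serum,V3,NA,NA,T4,130,0.87
brain,V1,2,frontal_cortex,NA,140,0.51
brain,V2,2,frontal_cortex,NA,140,0.44
brain,V3,2,frontal_cortex,NA,140,0.67
brain,V1,2,putamen,NA,150,0.22
brain,V2,2,putamen,NA,150,0.23
brain,V3,2,putamen,NA,150,0.47
serum,V1,NA,NA,T5,160,0.84
serum,V2,NA,NA,T5,160,0.84
serum,V3,NA,NA,T5,160,0.85
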