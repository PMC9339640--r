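check,plan,structure,value
mean,SOC,bowel,17.2
mean,3D,bowel,31.7
mean,SOC,heart,12.6
mean,3D,heart,10.0
mean,SOC,kidneys,1.6
mean,3D,kidneys,81.6
mean,SOC,lungs,4.2
mean,3D,lungs,52.6
mean,SOC,liver,2.3
mean,3D,liver,17.7
sd,SOC,bowel,9.8
sd,3D,bowel,7.7
sd,SOC,heart,6.9
sd,3D,heart,1.1
sd,SOC,kidneys,0.5
sd,3D,kidneys,8.8
sd,SOC,lungs,0.8
sd,3D,lungs,6.5
sd,SOC,liver,0.7
sd,3D,liver,5.9
reduction_vs_prescription,,lungs,95.8
reduction_vs_prescription,,kidneys,98.4
reduction_vs_prescription,,liver,97.7
reduction_vs_prescription,,bowel,82.8
reduction_vs_prescription,,heart,87.4
paired_reduction,,lungs,48.4
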