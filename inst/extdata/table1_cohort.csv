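patient,n_lesions,avg_distance_cm,gtv_cc,gtv_sd_cc,ptv_cc,ptv_sd_cc,adjacent_oar
I,2,2.2,2.2,0.78,3.70,1.10,Hippocampi
II,3,5.7,0.43,0.78,0.93,0.78,Hippocampi
III,4,6.5,3.90,5.20,6.50,8.30,Hippocampi; Optic apparatus
IV,5,8.9,3.30,3.30,4.90,4.30,Hippocampi
V,6,5.4,1.30,0.72,2.10,1.10,Hippocampi
VI,7,5.0,0.75,0.81,1.40,1.20,Brainstem; Hippocampi
VII,8,4.3,0.51,0.58,1.00,0.93,Brainstem; Hippocampi
VIII,10,5.5,0.39,0.46,0.86,0.46,Hippocampi
IX,16,5.4,0.43,0.63,0.83,1.00,Optic apparatus; Hippocampi; Brainstem
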