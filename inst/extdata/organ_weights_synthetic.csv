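organ,weight_g,sd_g
plasma,1.20,0.12
bone_marrow,0.25,0.03
rbc,1.10,0.11
spleen,0.09,0.01
liver,1.30,0.13
kidney,0.35,0.04
duodenum,0.25,0.03
intestine,1.80,0.18
stomach,0.25,0.03
integument,4.00,0.40
fat,1.50,0.20
muscle,9.50,0.95
lungs,0.15,0.02
brain,0.43,0.04
heart,0.13,0.01
testes,0.20,0.02
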