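item,points
psa_le6,0
psa_6_10,1
psa_10_20,2
psa_gt20,3
gleason_le33,0
gleason_34,1
gleason_43,2
gleason_8_10,3
margins,2
svi,2
ece,1
lni,1
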