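symbol,group,route,mean,half_width,kind
CS,all,both,0.283,0,fixed
AT,all,both,25550,0,fixed
CF,all,both,1e-6,0,fixed
ADAF,adult_trespasser,both,1,0,fixed
ADAF,child_trespasser,both,10,0,fixed
ADAF,adult_recreational,both,1,0,fixed
ADAF,child_recreational,both,10,0,fixed
BW,adult_trespasser,both,80,20,uniform
BW,child_trespasser,both,15,3.75,uniform
BW,adult_recreational,both,80,20,uniform
BW,child_recreational,both,15,3.75,uniform
EF,adult_trespasser,both,40,10,uniform
EF,child_trespasser,both,52,13,uniform
EF,adult_recreational,both,32,8,uniform
EF,child_recreational,both,48,12,uniform
ED,adult_trespasser,both,20,5,uniform
ED,child_trespasser,both,6,1.5,uniform
ED,adult_recreational,both,20,5,uniform
ED,child_recreational,both,6,1.5,uniform
IR_S,adult_trespasser,oral,20,5,uniform
IR_S,child_trespasser,oral,50,12.5,uniform
IR_S,adult_recreational,oral,20,5,uniform
IR_S,child_recreational,oral,50,12.5,uniform
FI,all,oral,1,0,fixed
AF,adult_trespasser,dermal,0.07,0.0175,uniform
AF,child_trespasser,dermal,0.2,0.05,uniform
AF,adult_recreational,dermal,0.2,0.05,uniform
AF,child_recreational,dermal,0.07,0.0175,uniform
ABSd,all,dermal,0.13,0,fixed
SA,adult_trespasser,dermal,6032,1508,uniform
SA,child_trespasser,dermal,2373,593.25,uniform
SA,adult_recreational,dermal,6032,1508,uniform
SA,child_recreational,dermal,2373,593.25,uniform
EV,all,dermal,1,0,fixed
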