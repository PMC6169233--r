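compound,route,csf
Benz(a)anthracene,oral,0.73
Benzo(a)pyrene,oral,7.3
Benzo(b)fluoranthene,oral,0.73
Benzo(k)fluoranthene,oral,0.073
Chrysene,oral,0.0073
"Dibenz(a,h)anthracene",oral,7.3
"Indeno(1,2,3-c,d)pyrene",oral,0.73
Benz(a)anthracene,dermal,2.5
Benzo(a)pyrene,dermal,25
Benzo(b)fluoranthene,dermal,2.5
Benzo(k)fluoranthene,dermal,0.25
Chrysene,dermal,0.025
"Dibenz(a,h)anthracene",dermal,25
"Indeno(1,2,3-c,d)pyrene",dermal,2.5
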