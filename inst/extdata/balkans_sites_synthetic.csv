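region_id,name,row,col
1,Thessaloniki,155,105
2,Philippoi,140,125
3,Nicopolis,170,55
4,Scupi,105,75
5,Traianoupolis,140,160
6,Dyrrachium,135,45
7,Heraclea,140,80
8,Constantinople,125,215
9,Marcianopolis,75,195
10,Serdica,80,115
11,Sirmium,15,55
12,Doclea,90,40
13,Remesiana,60,95
14,Hadrianopolis,115,175
15,Philippopolis,100,140
16,Singidunum,25,75
17,Tomis,45,215
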