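element	dar_pos	dar_neg	egfp
bmp2a+43k	Yes	Yes	No
chst3b+5k	Yes	Yes	Yes
cygb1-13k	Yes	Yes	Yes
dnajc17-138k	Yes	Yes	Yes
lef1-2k	Yes	Yes	No
pdgfab-8k	Yes	Yes	Yes
prdm1c+6k	Yes	Yes	Yes
runx1-102k	Yes	Yes	No
cdc42ep3+2k	Yes	No	Yes
col11a1a-6k	Yes	No	Yes
col11a2-7k	Yes	No	Yes
fam102aa+11k	Yes	No	Yes
fbln1+17k	Yes	No	Yes
mef2aa+2k	Yes	No	Yes
mitd1-6k	Yes	No	No
prdm5+120k	Yes	No	Yes
rmb7-120k	Yes	No	No
swap70b+3k	Yes	No	Yes
fhod3b+138k	No	Yes	Yes
frmd4a+87k	No	Yes	Yes
grip2a-23k	No	Yes	Yes
igflr1-2k	No	Yes	No
mtnr1aa+31k	No	Yes	Yes
ptk2aa+9k	No	Yes	Yes
rasl11a-13k	No	Yes	No
atp5g3a-14k	No	No	No
lmbr1+11k_ZRS	No	No	No
lnpa+56k	No	No	No
six3b-102k	No	No	No
six3b-104k	No	No	No
six3b-36k	No	No	No
six3b-39k	No	No	No
wnt3-11k	No	No	No
zgc:173726-2kb	No	No	No
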