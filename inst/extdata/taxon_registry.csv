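taxon,latin_name,common_name,expected_gestation_d,gestation_lo_d,gestation_hi_d,breeding_pattern,activity,active_dlc_breeding,n_biosample_individuals,origin_breeding_midmonth
CMED,Cheirogaleus medius,Fat-tailed dwarf lemur,60,60,64,S,N,Y,43,11
DMAD,Daubentonia madagascariensis,Aye-aye,165,157,172,NS,N,Y,34,
EALB,Eulemur albifrons,White-fronted brown lemur,120,120,128,S,D,N,5,6
ECOL,Eulemur collaris,Collared brown lemur,120,120,128,S,D,N,35,6
ECOR,Eulemur coronatus,Crowned lemur,120,120,126,S,D,Y,34,7
EFLA,Eulemur flavifrons,Blue-eyed black lemur,120,120,129,S,D,Y,,5
EFUL,Eulemur fulvus,Common brown lemur,120,120,128,S,D,N,7,6
EMAC,Eulemur macaco,Black lemur,120,120,129,S,D,N,,5
EMON,Eulemur mongoz,Mongoose lemur,120,120,128,S,D,Y,48,6
ERUB,Eulemur rubriventer,Red-bellied lemur,120,120,127,S,D,N,13,6
ERUF,Eulemur rufus,Red-fronted brown lemur,120,120,128,S,D,N,32,5
ESAN,Eulemur sanfordi,Sanford's brown lemur,120,120,128,S,D,N,11,7
EUL,Eulemur,Eulemur hybrid,120,120,128,S,D,N,41,6
GMOH,Galago moholi,Mohol bushbaby,124,110,126,NS,N,N,57,
HGG,Hapalemur griseus griseus,Eastern lesser bamboo lemur,145,145,150,S,D,N,34,6
LCAT,Lemur catta,Ring-tailed lemur,130,130,136,S,D,Y,122,5
LTAR,Loris tardigradus,Slender loris,167,150,169,NS,N,N,19,
MMUR,Microcebus murinus,Gray mouse lemur,60,57,63,S,N,Y,46,10
MZAZ,Mirza coquereli,Northern giant mouse lemur,90,89,90,NS,N,N,28,
NCOU,Nycticebus coucang,Slow loris,193,185,197,NS,N,N,24,
NPYG,Nycticebus pygmaeus,Pygmy slow loris,185,183,198,NS,N,Y,21,
OGG,Otolemur garnettii garnettii,Northern greater galago,129,126,134,NS,N,N,27,
PCOQ,Propithecus coquereli,Coquerel's sifaka,160,155,168,S,D,Y,85,3
PPOT,Perodicticus potto,Potto,170,170,172,NS,N,N,7,
VAR,Varecia,Varecia hybrid,98,98,102,S,D,N,2,7
VRUB,Varecia rubra,Red ruffed lemur,98,98,102,S,D,Y,53,7
VVV,Varecia variegata variegata,Black-and-white ruffed lemur,98,98,102,S,D,Y,43,7
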