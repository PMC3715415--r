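code	species
HSAP	Homo sapiens
MMUS	Mus musculus
TRUB	Takifugu rubripes
DRER	Danio rerio
CINT	Ciona intestinalis
BFLO	Branchiostoma floridae
CELE	Caenorhabditis elegans
DMEL	Drosophila melanogaster
AGAM	Anopheles gambiae
NVEC	Nematostella vectensis
TADH	Trichoplax adhaerens
MBRE	Monosiga brevicollis
BDEN	Batrachochytrium dendrobatidis
NCRA	Neurospora crassa
YLIP	Yarrowia lipolytica
DHAN	Debaryomyces hansenii
KLAC	Kluyveromyces lactis
CGLA	Candida glabrata
SCER	Saccharomyces cerevisiae
SPOM	Schizosaccharomyces pombe
CNEO	Cryptococcus neoformans
UMAY	Ustilago maydis
PBLA	Phycomyces blakesleeanus
RORY	Rhizopus oryzae
ECUN	Encephalitozoon cuniculi
EHIS	Entamoeba histolytica
DDIS	Dictyostelium discoideum
PFAL	Plasmodium falciparum
CPAR	Cryptosporidium parvum
TGON	Toxoplasma gondii
TTHE	Tetrahymena thermophila
PTET	Paramecium tetraurelia
PINF	Phytophthora infestans
PSOJ	Phytophthora sojae
PTRI	Phaeodactylum tricornutum
TPSE	Thalassiosira pseudonana
EHUX	Emiliania huxleyi
PPAT	Physcomitrella patens
ATHA	Arabidopsis thaliana
OSAT	Oryza sativa
SMOE	Selaginella moellendorffii
CREI	Chlamydomonas reinhardtii
VCAR	Volvox carteri
MPUS	Micromonas pusilla
OTAU	Ostreococcus tauri
CMER	Cyanidioschyzon merolae
LMAJ	Leishmania major
TBRU	Trypanosoma brucei
GINT	Giardia intestinalis
NGRU	Naegleria gruberi
TVAG	Trichomonas vaginalis
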