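name	major	minor
Pseudolucia tamara	clade_species	
Pseudolucia tamara Balint & Johnson, 1995	clade_species	
Thermus thermophilus (ex Oshima and Imahori 1974) Manaia et al. 1995	clade_species	
Oleria onega n. ssp. ME-2007	clade_species	
Botryllus_planus_DQ346653	clade_species	
Hypothyris_anastasia_20507	clade_species	
Myxine_glutinosa	clade_species	
Paramecium sp	clade_genus	
Gambierodiscus aff toxicus	clade_genus	
Angophora BOLD 7117	clade_genus	
Myxococcus Thaxter 1892 emend. Lang and Stackebrandt 2009	clade_genus	
Prochlorotrichaceae Burger-Wiersma et al. 1989	clade_higher	
Pyrenomycetes	clade_higher	
Sphingomonadaceae bacterium TPD06	clade_higher	
Puumala hantavirus	virus	
VESV	virus	
RTBV	virus	
Marek's disease virus (MDV)	virus	
Coconut tinangaja viroid	virus	
Prochlorococcus cyanophage P-GSP1	virus	
Yersinia pestis bacteriophage phiA1122	virus	
unassigned Alphaherpesvirinae	virus	
Influenza A virsu (A/Singapore/1/1957(H2N2))	virus	
Bovine viral diarrhea virus 2 C413	virus	
Human immunodeficiency virus type 2 D205	virus	
Stejneger's beaked whale gammaherpesvirus	virus	
Grandidier's Madagascar swift	common_name	
northern bottlenose whale	common_name	
terrible hairy fly	common_name	
daisy family	common_name	
blow flies	common_name	
laboratory rat	common_name	
depressed flour beetle	common_name	
tommy ruff	common_name	
Tommy rough	common_name	
Lyme disease spirochete	common_name	
host Paramecium tetraurelia 51KMJ	symbiont	
Zootermopsis hindgut protist	symbiont	
Alvinella pompejana symbiont APG1Bstab9	symbiont	
Incompatibility symbiont of Nasonia vitripennis	symbiont	
Chlorella symbiont of Hydra viridis	symbiont	
Onion yellows phytoplasma	symbiont	
Star grass white leaf phytoplasma	symbiont	
Lariskella endosymbiont of Curculio morimotoi	symbiont	
Urosporidium parasite of Stictodora lari	symbiont	
Euduboscquella sp. ex Favella markusovszkyi	symbiont	
Trypanosoma sp. from Abramis brama	symbiont	
Riftia pachyptila trophosome symbiont	symbiont	
strain KNic within Acanthamoeba castellanii	symbiont	
Magnolia heptapeta x Magnolia quinquepeta	hybrid	
x Cuprocyparis leylandii	hybrid	
x Aranda	hybrid	
Hordeum sp. x Triticum sp.	hybrid	
Malus x domestica	hybrid	
Sidalcea oregana subsp. oregana x Sidalcea asprella	hybrid	
domestic duck x muscovy duck	hybrid	
Gerbera hybridcultivar	hybrid	
not Bacteria Haeckel 1894	negated	
not Thiobacteria Cavalier-Smith 1998	negated	
non Lupinus argenteus J.Agardh, nom. illeg.	negated	
936	not_useful	numbered
1-Mar	not_useful	numbered
454594	not_useful	numbered
44AHJD-like phages	not_useful	numbered
24-pointed ladybird beetle	not_useful	numbered
16SrII (Peanut WB group)	not_useful	numbered
environmental samples	not_useful	environmental
coal metagenome	not_useful	environmental
tomb wall metagenome	not_useful	environmental
environmental clone CC-9	not_useful	environmental
corbulasulcata	not_useful	concatenated_unresolved
A. niger	not_useful	abbreviated
E. coli	not_useful	abbreviated
Rh. axei	not_useful	abbreviated
strain serial (Mueller et al.) n 189	not_useful	strain_surrogate
type strain 130333	not_useful	strain_surrogate
strain Royal Perth Hospital 13487	not_useful	strain_surrogate
strain=UTEX LB 1032	not_useful	strain_surrogate
ATCC 33224	not_useful	
NBRC 14945	not_useful	
CTEARO	not_useful	acronym
acroBioLep01 BioLep01	not_useful	
nucleomorph Pyrenomonas salina	not_useful	organelle
plastid Porphyridium aerugineum	not_useful	organelle
Intracisternal A-type particle IAP	not_useful	organelle
TOL plasmid	not_useful	plasmid
yeast plasmid pGKl2	not_useful	plasmid
promiscuous plasmids	not_useful	plasmid
Agrobacterium tumefaciens (TI PLASMID PTI15955)	not_useful	plasmid
Boolean Integrase Logic XNOR gate	not_useful	molecular
beta satellites	not_useful	molecular
artificial sequence	not_useful	molecular
Betasatellites	not_useful	molecular
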