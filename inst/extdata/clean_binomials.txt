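Ablepharus boutonii
Abudefduf saxatilis
Abudefduf septemfasciatus
Acacia catechu
Acanthurus leucosternon
Achromobacter georgiopolitanum
Aegilops triaristata
Aegiphila brachiata
Agrobacterium tumefaciens
Aleiantus incertus
Anabaena planktonica
Anguilla anguilla
Anolis barkeri
Anthaenantia villosa
Aphis citricida
Aphis citricidus
Aphis citricola
Asterina gibbosa
Athyma opalina
Athymna opalina
Bacillus gracilis
Bacillus gramineus
Bacillus graminis
Bacillus thuringiensi
Bacillus thuringiensis
Bacillus xiaoxiensis
Baileya australis
Bembidion concolor
Bison bison
Bombyx mori
Boreophyllum birdiae
Bothrops taeniata
Bothrops taeniatus
Brucella abortus
Bufo flavilineatus
Bufo flavolineatus
Burkholderia cenocepacia
Caestocorbula gerardi
Calonectria macroconidialis
Calonectria microconidialis
Candida guilliermondii
Carex appropinguata
Carex scirpoidea
Ceropegia anjanerica
Chilomonas paramecium
Cnemidophorus sackii
Cnemidophorus tigris
Coluber haje
Columbicola bacillus
Corbula cotuhensis
Corbula sulcata
Corchorus aestuans
Cryptoblepharus boutonii
Cryptomonas paramecium
Cucumis melo
Cupressocyparis leylandii
Cupressus macrocarpa
Cupressus nootkatensis
Cyanocitta stelleri
Danio rerio
Darevskia alpina
Darevskia daghestanica
Diaphanta chryseres
Didymostilbe sundara
Dorsophila melanogaster
Drosophila melangaster
Drosophila melanogaster
Emiliania huxleyi
Enteromorpha prolifera
Epichloe uncinata
Erigeron altaicus
Erigeron annuus
Erigeron canadensis
Erysimum odoratum
Escherichia coli
Euglossa cyanapis
Euglossa cyanaspis
Ficus ruginerva
Formosa crassostrea
Gallus gallus
Girardinia diversifolia
Glaucostegus thouin
Griffonia simplicifolia
Helicobacter pylori
Helicteres baruensis
Homo sapiens
Hyperamoeba dachnya
Hypocrea jecorina
Indigofera argentea
Indigofera grandiflora
Indigofera roseo-caerulea
Indigofera roseocaerulea
Inflabilis barati
Justicia carthagenensis
Justicia carthaginensis
Justicia catharinensis
Justicia charthaginensis
Kummerovia striata
Kummerowia striata
Lacerta capensis
Lacerta caucasica
Lacerta vivipara
Lasidioplodia pseudobromae
Lasiodiplodia pseudotheobromae
Lissoclinum timorense
Lobivia leptacantha
Lutzomyia hartmanni
Mageeibacillus indolicus
Melanocetus johnsoni
Melia azedarach
Meroles ctenodactylus
Microsporum canis
Monochamus galloprovincialis
Mucor miehei
Myxosoma cerebralis
Naja haje
Nepenthes xhookeriana
Oedipus lincolni
Owenia hilli
Owenia hillii
Oxalis adenophylla
Paludibacter propionicigenes
Papaver somnifera
Papaver somniferum
Parapercis lutevittata
Parapercis lutevittatus
Parathyma opalina
Pedioplanis laticeps
Phaeophleophleospora epicoccoides
Phaseolus vulgaris
Phaseoulus vulgaris
Pieris japonica
Plasmodium vivax
Populus maximowiczii
Porphyra purpurea
Pratia macrodon
Prorocentrum micans
Pseudallescheria africana
Pseudocosmospora eutypellae
Pseudolucia tamara
Pseudomonas syringae
Pyrus hybrida
Ranunculus mirus
Rattus rattus
Rhabditella axei
Rhinella spinulosa
Rosa hybrida
Rosa multiflora
Saccharomyces cerevisiae
Sargus bipunctatus
Sarracenia purpurea
Scincus boutonii
Sophophora melanogaster
Sphagnum affine
Sphagnum aureum
Sphagnum auriculatum
Sphagnum austinii
Sphagnum beringiense
Sphagnum bordasii
Sphagnum brasiliense
Sphagnum cribrosum
Sphagnum crispum
Sphagnum cymbifolioides
Sphagnum ecuadorense
Sphagnum inexspectatum
Sphagnum intermedium
Sphagnum kenaiense
Sphagnum khasianum
Sphagnum leonii
Sphagnum microcarpum
Sphagnum monzonense
Sphagnum nemoreum
Sphagnum palenae
Sphagnum patens
Sphagnum perfoliatum
Sphagnum pulchricoma
Sphagnum pycnocladum
Sphagnum sjorsii
Sphagnum tenerum
Sphagnum vitjianum
Sphagnum warnstorfii
Sphagnum wheeleri
Spinochlamydosporium variabile
Stagonosporopsis bohemica
Stauroneis legumen
Streptomyces cinnamoneus
Streptostele elgonensis
Syzggiam samaragense
Syzygium samarangense
Tasmanogobius lasti
Thermus thermophilus
Triactinomyxon gyrosalmo
Trichoderma reesei
Troglodyted troglodyted
Troglodytes troglodytes
Tsuchiaea wingfieldii
Tsuchiyeae wingfieldii
Ureaplasma urealyticum
Verbena mulinoides
Verena mulinoides
Vesicomya cordata
Xanthomonas populi
Zygrhablithus bijucatus
Zygrhablithus bijugatus
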