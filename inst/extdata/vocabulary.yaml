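# Term vocabularies used by the parser and the name-string classifier.
# The lists are deliberately editable: they are open-ended in real sources
# and can be extended per data source without touching code.

rank_markers:
  # infraspecific / infrasubspecific rank markers; attach to the epithet
  # that follows them
  - "ssp."
  - "ssp"
  - "subsp."
  - "subsp"
  - "var."
  - "var"
  - "subvar."
  - "f."
  - "fo."
  - "forma"
  - "f.sp."
  - "subf."
  - "morph."
  - "mut."
  - "nat"
  - "nothosubsp."
  - "nothovar."
  - "convar."
  - "pseudovar."
  - "sect."
  - "ser."
  - "race"
  - "cv."
  - "pv."

greek_rank_letters:
  # accepted as infrasubspecific markers only after a valid binomial
  - "α"
  - "β"
  - "γ"
  - "δ"
  - "ε"
  - "φ"
  - "θ"
  - "μ"
single_letter_ranks: ["a", "b", "c", "d", "e", "g", "k"]

annotations:
  sp_indet: ["sp.", "sp", "spp.", "spp", "spec.", "species", "gen.", "indet."]
  cf: ["cf.", "cf", "cfr."]
  aff: ["aff.", "aff"]
  nr: ["nr.", "nr"]
  negation: ["non", "nec", "not", "null"]
  sensu_auct: ["sensu", "auct.", "auctt.", "sec.", "s.l.", "s.s.", "s.str."]
  cultivar: ["cultivar", "hybrid"]
  strain_marker: ["str.", "strain", "isolate", "clone", "culture"]
  emend: ["emend.", "emend", "corrig."]
  in_part: ["p.p.", "pro parte"]

# multi-token annotations matched as regular expressions on the whole string
annotation_patterns:
  nom_status: "\\bnom\\.\\s*(illeg|superfl|rej|cons|nud|nov)\\.?"
  sensu_auct: "\\bsensu\\s+(lato|stricto|auctt?\\.?)"

classifier:
  virus_terms:
    - "virus"
    - "viruses"
    - "virsu"          # a recurring misspelling in real sources
    - "viroid"
    - "phage"
    - "bacteriophage"
    - "cyanophage"
    - "prophage"
    - "provirus"
  virus_patterns:
    - "\\w+(virus|viridae|virinae|virales)\\b"
    - "\\b[A-Z][A-Za-z]*[A-Z]V\\b"        # terminal-V acronyms (RTBV, ArceNPV)
    - "\\bNPV\\b"
    - "\\bICTV\\b"
  symbiont_terms:
    - "symbiont"
    - "endosymbiont"
    - "ectosymbiont"
    - "photobiont"
    - "trophosome"
    - "phytoplasma"
    - "phytoplasm"
    - "parasite"
    - "host"
    - "hindgut"
    - "mycorrhiza"
    - "mycorrhizae"
    - "mycorrhizal"
  symbiont_patterns:
    - "\\bsp\\.?\\s+(ex|from)\\b"
    - "\\bex\\s+[A-Z][a-z]+\\s+[a-z]{3,}$"
    - "\\bof\\s+[A-Z][a-z]+\\s+[a-z]{3,}"
    - "\\bassociated\\b"
    - "\\bwithin\\s+[A-Z][a-z]+"
  environmental_terms:
    - "environmental samples"
    - "environmental sample"
    - "environmental clone"
    - "metagenome"
    - "enrichment culture"
    - "landfill"
    - "soil organism"
    - "phytodetritus"
    - "mycorrhizal samples"
  higher_rank_suffixes:
    - "idae"
    - "aceae"
    - "ales"
    - "formes"
    - "oidea"
    - "oidei"
    - "phyta"
    - "phyceae"
    - "mycota"
    - "mycetes"
    - "archaeota"
    - "bacteria"
    - "inae"
    - "ini"
  higher_rank_names:
    - "Bacteria"
    - "Archaea"
    - "Fungi"
    - "Metazoa"
    - "Insecta"
    - "Mammalia"
    - "Aves"
    - "Reptilia"
    - "Amphibia"
    - "Biota"
    - "Eukaryota"
    - "Viridiplantae"
    - "Lepidoptera"
    - "Coleoptera"
    - "Diptera"
    - "Crustacea"
    - "Mollusca"
    - "Nematoda"
    - "Annelida"
    - "Cnidaria"
    - "Porifera"
    - "Chordata"
    - "Arthropoda"
    - "Pyrenomycetes"
  organelle_terms:
    - "mitochondrion"
    - "mitochondrial"
    - "chloroplast"
    - "plastid"
    - "nucleomorph"
    - "intracisternal"
  plasmid_terms:
    - "plasmid"
    - "plasmids"
    - "plasposon"
    - "vector"
  molecular_terms:
    - "satellite"
    - "satellites"
    - "betasatellite"
    - "betasatellites"
    - "dsrna"
    - "ssrna"
    - "construct"
    - "integrase"
    - "t-dna"
    - "artificial sequence"
    - "nucleic acid"
    - "transposable"
    - "transconjugant"
  strain_collection_codes:
    - "ATCC"
    - "CBS"
    - "NBRC"
    - "UTEX"
    - "CCUG"
    - "JCM"
    - "DSM"
    - "DSMZ"
    - "CIP"
    - "NCTC"
    - "IMI"
    - "CCAP"
    - "SAG"
    - "BOLD"
  common_words:
    - "bat"
    - "whale"
    - "frog"
    - "toad"
    - "fish"
    - "fishes"
    - "shark"
    - "ray"
    - "bird"
    - "duck"
    - "goose"
    - "shrew"
    - "mouse"
    - "rat"
    - "civet"
    - "mongoose"
    - "salamander"
    - "newt"
    - "snake"
    - "lizard"
    - "beetle"
    - "beetles"
    - "fly"
    - "flies"
    - "flly"
    - "wasp"
    - "bee"
    - "ant"
    - "moth"
    - "butterfly"
    - "shrimp"
    - "shrim"
    - "crab"
    - "worm"
    - "worms"
    - "snail"
    - "clam"
    - "oyster"
    - "mushroom"
    - "fungus"
    - "grass"
    - "grasses"
    - "tree"
    - "trees"
    - "family"
    - "group"
    - "lineages"
    - "clade"
    - "monocotyledons"
    - "spirochete"
    - "spirochetes"
    - "nematode"
    - "caterpillar"
    - "grenadier"
    - "tyrant"
    - "dory"
    - "swift"
    - "flea"
    - "asp"
    - "jackrabbit"
    - "bluebells"
    - "rockcress"
    - "salmon"
    - "trout"
    - "carp"
    - "bream"
    - "tongues"
    - "wave"
    - "barf"
    - "cross"
    - "clock"
    - "medics"
    - "ruff"
    - "rough"
    - "moss"
    - "wolf"
    - "bear"
    - "seal"
    - "disease"
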