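Aotus
Peranema
Dolium
Pieris japonica
Asterina gibbosa
Baileya australis
Agathis
Morus
Prunella
Oenanthe
Ricinus
Alsophila
Erica
Dryas
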