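# Default German symptom normalization dictionary.
# Two columns: canonical<TAB>variant (one variant per line).
# Variants enumerate synonyms and inflected forms; matching is
# case-insensitive. Canonicals are implicitly variants of themselves.
Obstipation	Verstopfung
Obstipation	verstopft
Husten	husten
Husten	gehustet
Husten	Hustenreiz
Dyspnoe	Atemnot
Dyspnoe	Luftnot
Dyspnoe	dyspnoisch
Fieber	febril
Fieber	fiebrig
Fieber	Temperatur erhöht
Übelkeit	Nausea
Übelkeit	übel
Erbrechen	erbrochen
Erbrechen	Emesis
Schwindel	schwindelig
Schwindel	Vertigo
Diarrhö	Durchfall
Diarrhö	Diarrhoe
Schwellung	geschwollen
Rötung	gerötet
Überwärmung	überwärmt
Kopfschmerzen	Cephalgie
Kopfschmerzen	Kopfschmerz
Kopfschmerzen	Zephalgie
Thoraxschmerzen	Thoraxschmerz
Thoraxschmerzen	Brustschmerzen
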