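# Demonstration lexicon: form <TAB> baseform [<TAB> part1|part2|...]
# English inflected forms
clips	clip
stents	stent
occluders	occluder
implants	implant
devices	device
complications	complication
failures	failure
failed	fail
fails	fail
incidents	incident
risks	risk
studies	study
animals	animal
events	event
reports	report
reported	report
reporting	report
patients	patient
materials	material
alloys	alloy
systems	system
queries	query
searches	search
screening	screen
screened	screen
implanted	implant
implantation	implant
clipping	clip
clipped	clip
# German inflected forms
Komplikationen	Komplikation
Zwischenfälle	Zwischenfall
Studien	Studie
Tiere	Tier
Implantate	Implantat
Geräte	Gerät
Risiken	Risiko
Werkstoffe	Werkstoff
Berichte	Bericht
Patienten	Patient
Legierungen	Legierung
# German compounds (baseform <TAB> parts)
Qualitätskontrolle	Qualitätskontrolle	Qualität|Kontrolle
Herzschrittmacher	Herzschrittmacher	Herz|Schrittmacher
Magenspiegelung	Magenspiegelung	Magen|Spiegelung
Nickellegierung	Nickellegierung	Nickel|Legierung
Formgedächtnislegierung	Formgedächtnislegierung	Formgedächtnis|Legierung
Medizinprodukt	Medizinprodukt	Medizin|Produkt
Medizinprodukte	Medizinprodukt	Medizin|Produkt
Risikoanalyse	Risikoanalyse	Risiko|Analyse
Marktüberwachung	Marktüberwachung	Markt|Überwachung
Zwischenfallbericht	Zwischenfallbericht	Zwischenfall|Bericht
Clipsystem	Clipsystem	Clip|System
Clipsysteme	Clipsystem	Clip|System
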