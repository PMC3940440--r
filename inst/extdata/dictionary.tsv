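# packaged ecology dictionary: stem key <TAB> concept URI
# stems are deliberately truncated so one entry covers all inflections
predat	http://dbpedia.org/resource/Predation
herbivor	http://dbpedia.org/resource/Herbivore
parasit	http://dbpedia.org/resource/Parasitism
pollinat	http://dbpedia.org/resource/Pollination
migrat	http://dbpedia.org/resource/Animal_migration
hibernat	http://dbpedia.org/resource/Hibernation
nocturn	http://dbpedia.org/resource/Nocturnality
symbio	http://dbpedia.org/resource/Symbiosis
carnivor	http://dbpedia.org/resource/Carnivore
omnivor	http://dbpedia.org/resource/Omnivore
scaveng	http://dbpedia.org/resource/Scavenger
burrow	http://dbpedia.org/resource/Burrow
venom	http://dbpedia.org/resource/Venom
spawn	http://dbpedia.org/resource/Spawn_(biology)
forest	http://dbpedia.org/resource/Forest
marine	http://dbpedia.org/resource/Ocean
estuar	http://dbpedia.org/resource/Estuary
plankt	http://dbpedia.org/resource/Plankton
echolocat	http://dbpedia.org/resource/Animal_echolocation
cannibal	http://dbpedia.org/resource/Cannibalism_(zoology)
gestat	http://dbpedia.org/resource/Gestation
ovovivipar	http://dbpedia.org/resource/Ovoviviparity
camoufl	http://dbpedia.org/resource/Camouflage
uterine cannibalism	http://dbpedia.org/resource/Oophagy
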