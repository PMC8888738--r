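clade,crown_age_myr,note
Spermatophyta,350,angiosperm-gymnosperm split (fixed reference value)
Gymnospermae,273,Cupressales-Pinales split (fixed reference value)
Angiospermae,140,placeholder age - edit from systematics literature
Pinales,200,placeholder
Cupressales,210,placeholder
Fagales,96,placeholder
Sapindales,88,placeholder
Malpighiales,92,placeholder
Rosales,94,placeholder
Lamiales,72,placeholder
Malvales,78,placeholder
Myrtales,100,placeholder
Fabales,98,placeholder
Pinaceae,155,placeholder
Cupressaceae,160,placeholder
Fagaceae,70,placeholder
Betulaceae,72,placeholder
Sapindaceae,60,placeholder
Salicaceae,65,placeholder
Rosaceae,80,placeholder
Oleaceae,55,placeholder
Malvaceae,58,placeholder
Myrtaceae,68,placeholder
Fabaceae,74,placeholder
Pinus,70,placeholder
Picea,28,placeholder
Abies,35,placeholder
Quercus,40,placeholder
Betula,30,placeholder
Alnus,32,placeholder
Acer,45,placeholder
Populus,35,placeholder
Eucalyptus,52,placeholder
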