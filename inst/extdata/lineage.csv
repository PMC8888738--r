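species,genus,family,order,class
Pinus sylvestris,Pinus,Pinaceae,Pinales,Gymnospermae
Pinus pinaster,Pinus,Pinaceae,Pinales,Gymnospermae
Pinus radiata,Pinus,Pinaceae,Pinales,Gymnospermae
Pinus contorta,Pinus,Pinaceae,Pinales,Gymnospermae
Picea abies,Picea,Pinaceae,Pinales,Gymnospermae
Picea sitchensis,Picea,Pinaceae,Pinales,Gymnospermae
Picea glauca,Picea,Pinaceae,Pinales,Gymnospermae
Abies alba,Abies,Pinaceae,Pinales,Gymnospermae
Abies grandis,Abies,Pinaceae,Pinales,Gymnospermae
Larix decidua,Larix,Pinaceae,Pinales,Gymnospermae
Larix kaempferi,Larix,Pinaceae,Pinales,Gymnospermae
Pseudotsuga menziesii,Pseudotsuga,Pinaceae,Pinales,Gymnospermae
Cupressus lusitanica,Cupressus,Cupressaceae,Cupressales,Gymnospermae
Juniperus communis,Juniperus,Cupressaceae,Cupressales,Gymnospermae
Thuja plicata,Thuja,Cupressaceae,Cupressales,Gymnospermae
Sequoia sempervirens,Sequoia,Cupressaceae,Cupressales,Gymnospermae
Quercus robur,Quercus,Fagaceae,Fagales,Angiospermae
Quercus petraea,Quercus,Fagaceae,Fagales,Angiospermae
Quercus rubra,Quercus,Fagaceae,Fagales,Angiospermae
Fagus sylvatica,Fagus,Fagaceae,Fagales,Angiospermae
Castanea sativa,Castanea,Fagaceae,Fagales,Angiospermae
Betula pendula,Betula,Betulaceae,Fagales,Angiospermae
Betula pubescens,Betula,Betulaceae,Fagales,Angiospermae
Alnus glutinosa,Alnus,Betulaceae,Fagales,Angiospermae
Alnus incana,Alnus,Betulaceae,Fagales,Angiospermae
Carpinus betulus,Carpinus,Betulaceae,Fagales,Angiospermae
Nothofagus obliqua,Nothofagus,Nothofagaceae,Fagales,Angiospermae
Nothofagus dombeyi,Nothofagus,Nothofagaceae,Fagales,Angiospermae
Acer platanoides,Acer,Sapindaceae,Sapindales,Angiospermae
Acer pseudoplatanus,Acer,Sapindaceae,Sapindales,Angiospermae
Populus tremula,Populus,Salicaceae,Malpighiales,Angiospermae
Populus nigra,Populus,Salicaceae,Malpighiales,Angiospermae
Salix alba,Salix,Salicaceae,Malpighiales,Angiospermae
Prunus avium,Prunus,Rosaceae,Rosales,Angiospermae
Sorbus aucuparia,Sorbus,Rosaceae,Rosales,Angiospermae
Fraxinus excelsior,Fraxinus,Oleaceae,Lamiales,Angiospermae
Tilia cordata,Tilia,Malvaceae,Malvales,Angiospermae
Eucalyptus globulus,Eucalyptus,Myrtaceae,Myrtales,Angiospermae
Eucalyptus grandis,Eucalyptus,Myrtaceae,Myrtales,Angiospermae
Robinia pseudoacacia,Robinia,Fabaceae,Fabales,Angiospermae
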