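taxon,body_mass_kg_min,body_mass_kg_max,endocast_volume_ml_min,endocast_volume_ml_max,fill_fractions,density_g_per_ml,annotation
Thescelosaurus neglectus,339,339,27.25,28.61,0.5;0.6,1.036,
Kentrosaurus aethiopicus,1600,1600,48,48,0.5;0.6,1.036,
Stegosaurus stenops,2000,6950,45,56,0.5;0.6,1.036,
Euoplocephalus tutus,2330,2330,82,82,0.5;0.6,1.036,
Camptosaurus dispar,400,400,46,46,0.5;0.6,1.036,
Lurdusaurus arenatus,4190,4190,167,167,0.5;0.6,1.036,
Proa valdearinnoensis,3560,3560,316,316,0.5;0.6,1.036,source values not reproducible from these inputs
Iguanodon bernissartensis,8270,8270,357,357,0.5;0.6,1.036,
Mantellisaurus atherfieldensis,1430,1430,131,131,0.5;0.6,1.036,lower bound (+)
Edmontosaurus sp.,3400,6610,300,300,0.5;0.6,1.036,
Amurosaurus riabinini,4790,4790,290,290,0.5;0.6,1.036,
Hypacrosaurus altispinus,3690,3690,275.9,275.9,0.5;0.6,1.036,
Psittacosaurus lujiatunensis,25,25,14.3,14.3,0.5;0.6,1.036,
Protoceratops andrewsi,82.7,82.7,30,30,0.5;0.6,1.036,
Triceratops sp.,6000,13540,140,140,0.5;0.6,1.036,
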