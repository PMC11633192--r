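# Reference N2O isotopocule dataset: strain means (SD) from NO3-/NO2- reduction
# by Geobacteraceae strains and an abiotic control. d15N_bulk and d18O are
# substrate-referenced (product minus substrate); SP is reference-frame free.
substrate,strain,genus,day,d18O,d18O_sd,d15N_bulk,d15N_bulk_sd,SP,SP_sd,biotic
NO3,Geomonas sp. Red32,Geomonas,3,16.2,0.1,-39.8,0,46.5,0.1,TRUE
NO3,Geomonas sp. Red32,Geomonas,7,14.6,0.4,-27.5,1.2,45.4,1.4,TRUE
NO3,G. diazotrophica Red69,Geomonas,3,26.4,4.1,-29.6,4.5,45.5,0.7,TRUE
NO3,G. diazotrophica Red69,Geomonas,7,23.6,3.9,-28.2,4.9,41.9,0.9,TRUE
NO3,G. terrae Red111,Geomonas,3,15.2,1.2,-19.7,2.1,47.0,0.3,TRUE
NO3,G. terrae Red111,Geomonas,7,9.6,0.7,-23.0,3.4,41.1,1.4,TRUE
NO3,G. silvestris Red330,Geomonas,3,18.6,4.1,-21.1,7.0,46.8,1.3,TRUE
NO3,G. silvestris Red330,Geomonas,7,15.5,1.5,-18.0,7.2,46.5,0.1,TRUE
NO3,O. rubra Red88,Oryzomonas,3,23.4,0.8,-31.4,3.7,46.3,0.6,TRUE
NO3,O. rubra Red88,Oryzomonas,7,19.2,1.5,-22.4,5.4,46.4,0.3,TRUE
NO2,Geomonas sp. Red32,Geomonas,3,27.8,0.2,-23.7,0,46.8,0.2,TRUE
NO2,Geomonas sp. Red32,Geomonas,7,27.0,1.0,-21.3,0.1,46.1,1.0,TRUE
NO2,G. diazotrophica Red69,Geomonas,3,28.8,0.1,-23.7,0,45.8,0.7,TRUE
NO2,G. diazotrophica Red69,Geomonas,7,28.6,0,-23.5,0.3,46.0,0.1,TRUE
NO2,G. terrae Red111,Geomonas,3,27.5,0.3,-24.3,0.1,47.2,0.7,TRUE
NO2,G. terrae Red111,Geomonas,7,29.5,0,-23.9,0.1,46.3,0.2,TRUE
NO2,G. silvestris Red330,Geomonas,3,28.5,0.4,-22.5,0.5,46.5,0.2,TRUE
NO2,G. silvestris Red330,Geomonas,7,28.6,0.2,-21.6,0.5,46.4,0.2,TRUE
NO2,O. rubra Red88,Oryzomonas,3,28.8,0.4,-21.6,0.7,44.8,2.0,TRUE
NO2,O. rubra Red88,Oryzomonas,7,28.8,0.3,-21.0,0.1,44.4,2.0,TRUE
NO2,G. bemidjiensis DSM 16622,Geomonas,3,28.6,0.6,-22.9,0.2,47.4,2.3,TRUE
NO2,Geob. anodireducens JCM 30203,Geobacter,3,28.7,0.7,-23.0,0,46.7,0.7,TRUE
NO2,Abiotic,abiotic,1,20.1,0.2,-28.8,0.4,20.0,1.2,FALSE
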