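ligand,pubchem_cid
chebulagic acid,442674
chebulinic acid,72284
gallic acid,370
punicalagin,44584733
isoterchebulin,16143735
beta-sitosterol,222284
ellagic acid,5281855
chebulic acid,12302892
shikimic acid,8742
dehydroshikimic acid,5460360
quinic acid,6508
triacontanoic acid,10471
corilagin,73568
maslinic acid,73659
arjunolic acid,73641
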