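target,chebulagic acid,chebulinic acid,gallic acid,punicalagin,isoterchebulin,beta-sitosterol,ellagic acid,chebulic acid,shikimic acid,dehydroshikimic acid,quinic acid,triacontanoic acid,corilagin,maslinic acid,arjunolic acid
COX-2,16.1,13.7,6.1,17.1,15.8,6.7,23.8,6.9,6,6.1,6,4.2,9.5,8.9,7.9
5-LOX,14.6,14.3,6.4,16.7,16.2,7.9,9,7,6.5,6.3,6.1,6.7,9.2,8.4,8.1
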