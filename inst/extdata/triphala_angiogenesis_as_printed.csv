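target,chebulagic acid,chebulinic acid,gallic acid,punicalagin,isoterchebulin,beta-sitosterol,ellagic acid,chebulic acid,shikimic acid,dehydroshikimic acid,quinic acid,triacontanoic acid,corilagin,maslinic acid,arjunolic acid
VEGF A,-14.3,-12.1,-6,-16.1,-14.7,-7.1,-7.4,-6.7,-5.9,-5.6,-6,-5,-8.6,-7.6,-7.7
VEGF R1,-13.6,-11.6,-5.7,-14.4,-13.1,-6.5,-6.9,-6.9,-5.5,-5.5,-5.6,-4.2,-7.8,-7.4,-8.1
VEGFR2,-15.4,-15.1,-5,-15.7,-15.3,-8,-7.8,-6,-4.8,-5,-5,-5.3,-7.9,-8.2,-7.8
NRP 1,-17.9,-15.2,-6.2,-17.4,-16.6,-7.5,-8.4,-6.7,-5.7,-5.7,-5.6,-5,-8.7,-7.7,-7.4
NRP 2,-14.6,-12.9,-5.6,-15,-14.1,-7.3,-7.2,-6.9,-5.2,-5.2,-5.7,-4.2,-9,-8.5,-7.4
PKC gamma,-13,-12.6,-7.1,-15.3,-14.5,-6,-10.6,-6.8,-7.1,-7.2,-7.6,-6.2,-8.1,-8,-7.5
RAS,-13,-12,-5.4,-13.7,-13.8,-6.1,-6.7,-6.1,-4.8,-5,-5.1,-4,-7.9,-6.4,-6.2
RAF 1,-20.4,-14.6,-6.2,-15.1,-14.1,-8.6,-8.7,-8.2,-6.7,-6.7,-6.4,-6.8,-7.6,-8.9,-8
MEK,-14.5,-14.7,-6.2,-16.2,-16,-7.1,-8.7,-7.7,-5.8,-5.8,-5.8,-4.8,-9.9,-8.3,-7.8
ERK,-14,-12.7,-6.5,-14.4,-13.1,-7.7,-7.9,-6.9,-6.5,-6.5,-6.9,-5.5,-8.5,-7.9,-7.5
PLC gamma,-16.6,-14.4,-5.9,-17.9,-16.8,-7.7,-7.3,-6.4,-5.3,-5.8,-5.7,-4.7,-8.7,-9.4,-8.8
FAK,-13.7,-12.2,-5.7,-15.8,-14.9,-7.2,-9.2,-6.7,-5.2,-5.9,-5.3,-5.3,-8.7,-8.3,-7.9
Cdc42,-14.3,-12.7,-5.8,-15,-14.2,-6.9,-7.7,-6.6,-5.5,-5.9,-5.8,-6.9,-8.2,-8.1,-7.7
p38MAPK,-15.3,-13.2,-5.6,-15,-14.2,-8,-8.4,-7.4,-5.6,-5.6,-5.9,-6.6,-8.1,-9.1,-8.2
MAPKAPK,-16.5,-12.4,-5.9,-20,-17.8,-7.5,-9.2,-6.6,-5.6,-6.1,-5.4,-4.6,-7.3,-8.5,-8.5
SRC,-14.9,-12.7,-5.5,-15.2,-13.6,-6.5,-8.1,-7.4,-5.4,-5.1,-5.7,-4.3,-8.8,-7.9,-7.9
PI3K,-18.4,-15.2,-6.3,-17.2,-16.1,-8.7,-8.8,-8.5,6.4,-6.3,-6.6,-5.7,-10,-9.2,-9.4
RAC,-12.7,-10.8,-5,-13.3,-12.5,-6.7,-7,-6,-4.8,-4.8,-5.4,-3.4,-7.1,-7.2,-7.3
AKT/PKB,-17.8,-15.3,-6.2,-17.9,-17.3,-8,-8.3,-7.3,-6,-6.1,-6.5,-5.1,-9.9,-9.4,-9.2
eNOS,-18,-16.9,-7.1,-19.5,-17.3,-9.4,-8.8,-7.6,-6.6,-7,-7,-6.3,-9.7,-9.1,-9
paxillin,-19.1,-13.9,-6.4,-16.8,-15.7,-8.8,-10.3,-7.8,-6.2,-6.7,-6.1,-6.2,-8.7,-9.1,-8.8
Hsp27,-12.1,-11.1,-5.1,-12.6,-12.3,-6.2,-7,-5.5,4.6,-5.2,-4.5,-5.2,-6.9,-7,-6.9
axin,-13.4,-12.3,-4.9,-14.2,-13.7,-6.4,-7,-5.9,-5,-4.7,-4.9,-3.8,-7.9,-7.8,-7.4
GSK 3beta,-17.1,-14.9,-6.9,-18.4,-18.4,-8.8,-8.2,-7,-7,-7.1,-7.4,-5.9,-9.4,-9.5,-8.7
beta-catenin,-14.4,-12,-5.6,-12.2,-11.1,-5.1,-6.1,-5.6,-4.9,-5,-4.8,-3.9,-6.6,-6.1,-5.9
MMP9,-16.5,-13.7,-7.2,-17.1,-16.5,-7.9,-9,-7.7,-6.9,-6.9,-7.1,-5.5,-8.7,-8.5,-8.3
MMP3,-13.9,-13.1,-5.4,-15.7,-15.3,-7.1,-7,-6.4,-5,-5.2,-5,-4.6,-8.6,-8.2,-8.2
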