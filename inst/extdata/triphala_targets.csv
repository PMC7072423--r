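target,pdb_id,panel
VEGF A,1VPF,angiogenesis
VEGF R1,1RV6,angiogenesis
VEGFR2,1Y6A,angiogenesis
NRP 1,2QQM,angiogenesis
NRP 2,2QQO,angiogenesis
PKC gamma,2UZP,angiogenesis
RAS,5P21,angiogenesis
RAF 1,3OMV,angiogenesis
MEK,3EQC,angiogenesis
ERK,2Y9QP,angiogenesis
PLC gamma,4EY0,angiogenesis
FAK,4I4E,angiogenesis
Cdc42,2KBO,angiogenesis
p38MAPK,1W82,angiogenesis
MAPKAPK,3FHR,angiogenesis
SRC,1A1C,angiogenesis
PI3K,3ZIM,angiogenesis
RAC,1MH1,angiogenesis
AKT/PKB,2X18,angiogenesis
eNOS,1M9M,angiogenesis
paxillin,2VZI,angiogenesis
Hsp27,3Q9P,angiogenesis
axin,1EMU,angiogenesis
GSK 3beta,1Q3W,angiogenesis
beta-catenin,1LUJ,angiogenesis
MMP9,1L6J,angiogenesis
MMP3,1UEA,angiogenesis
COX-2,3LN1,inflammation
5-LOX,3O8Y,inflammation
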