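{
  "comment": "Documented corrections to the Triphala screening matrices as printed. Values are in canonical signed kcal/mol (after magnitude negation for the inflammation panel). Corrections are applied only by the *_errata fixture variants; the *_as_printed variants ship every cell verbatim.",
  "angiogenesis": [
    {
      "ligand": "shikimic acid",
      "target": "PI3K",
      "as_printed": 6.4,
      "corrected": -6.4,
      "note": "Printed without a minus sign; all affinities in this screen are favorable, and negating this cell (together with the Hsp27 cell) reconstructs shikimic acid's published prediction efficacy of -59.4."
    },
    {
      "ligand": "shikimic acid",
      "target": "Hsp27",
      "as_printed": 4.6,
      "corrected": -4.6,
      "note": "Printed without a minus sign; see the PI3K entry. The corrected value still fails the -6.0 kcal/mol pass filter."
    }
  ],
  "inflammation": [
    {
      "ligand": "ellagic acid",
      "target": "COX-2",
      "as_printed": -23.8,
      "corrected": -8.0,
      "note": "The printed magnitude 23.8 contradicts ellagic acid's published prediction efficacy of -17 over COX-2 and 5-LOX; -8.0 is the unique value consistent with it given the 5-LOX affinity of -9.0."
    }
  ]
}
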