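# Drug definitions for the two benzodiazepine analytes.
# pKa ladders are ordered ascending; charges run from the most protonated
# species to the least (each step removes one proton).
nitrazepam:
  pka: [3.2, 10.8]
  charges: [1, 0, -1]
  labels: [NIT+, NIT0, NIT-]
  molar_mass: 281.27
7-aminonitrazepam:
  pka: [2.5, 4.6, 13.1]
  charges: [2, 1, 0, -1]
  labels: [7a-NIT2+, 7a-NIT+, 7a-NIT0, 7a-NIT-]
  molar_mass: 251.28
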