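{
  "comment": "Default AOX curation catalog. signature_motifs, tbaox cavity/dimer positions and letters, and the MDM regulator motifs are transcribed from published curation tables. The diiron position list, the diagnostic allowed-residue sets and the synthetic reference coordinates are synthetic defaults (synthetic_default: true) matching the package's synthetic reference scaffold; override them for real data.",
  "signature_motifs": [
    { "name": "LETVAA",  "pattern": "LETVAA",  "catalytic": [2] },
    { "name": "ERMHLMT", "pattern": "ERMHLMT", "catalytic": [1, 4] },
    { "name": "LEEEA",   "pattern": "LEEEA",   "catalytic": [2, 3, 4] },
    { "name": "RADEAHH", "pattern": "RADEAHH", "catalytic": [4, 6, 7] }
  ],
  "diagnostic_scheme": {
    "reference_id": "refAOX1a.synthetic",
    "synthetic_default": true,
    "type_positions": {
      "112": { "Type1": ["L"], "Type2": ["F"] },
      "124": { "Type1": ["P"], "Type2": ["T"] },
      "229": { "Type1": ["N"], "Type2": ["S"] },
      "233": { "Type1": ["A"], "Type2": ["G"] },
      "241": { "Type1": ["E"], "Type2": ["D"] }
    },
    "subtype_positions": {
      "167": { "ace": ["M"], "d": ["M", "V"] },
      "175": { "ace": ["T"], "d": ["A"] },
      "178": { "ace": ["Y"], "d": ["W"] },
      "180": { "ace": ["R"], "d": ["R"] },
      "181": { "ace": ["A"], "d": ["A"] },
      "295": { "ace": ["S"], "d": ["N"] }
    }
  },
  "tbaox_positions": {
    "diiron": [62, 149, 152, 170, 216, 218, 219],
    "dimer_core": [138, 142, 143, 163, 166, 187],
    "dimer_high": [131, 135, 139, 141, 145, 147, 148, 156, 159, 167, 180, 183],
    "cavity": [91, 94, 95, 97, 98, 99, 102, 117, 118, 121, 122, 125, 126, 128,
               178, 179, 181, 182, 185, 186, 189, 190, 193, 194, 197, 198,
               200, 201, 204, 205, 208, 209, 212]
  },
  "tbaox_residues": {
    "62": "E", "149": "E", "152": "H", "170": "E", "216": "E", "218": "H",
    "219": "H",
    "91": "S", "94": "T", "95": "C", "97": "W", "98": "L", "99": "F",
    "102": "F", "117": "S", "118": "R", "121": "F", "122": "L", "125": "V",
    "126": "A", "128": "V", "178": "P", "179": "L", "181": "V", "182": "S",
    "185": "I", "186": "T", "189": "I", "190": "M", "193": "F", "194": "L",
    "197": "A", "198": "Y", "200": "I", "201": "S", "204": "F", "205": "V",
    "208": "F", "209": "V", "212": "L",
    "138": "H", "142": "L", "143": "R", "163": "R", "166": "L", "187": "Q",
    "131": "M", "135": "M", "139": "L", "141": "S", "145": "M", "147": "R",
    "148": "D", "156": "L", "159": "A", "167": "M", "180": "R", "183": "I"
  },
  "regulator_motifs": [
    { "name": "MDM_stringent",   "pattern": "CTTGNNNNNCAMG", "role": "positive",
      "category": "mitochondrial_retrograde" },
    { "name": "MDM_alternative", "pattern": "YTTGNNNNNVAMV", "role": "positive",
      "category": "mitochondrial_retrograde" }
  ],
  "chemistry_map": {
    "hydrophobic": ["A", "V", "L", "I", "M", "C"],
    "polar": ["S", "T", "N", "Q", "D", "E", "K", "R"],
    "cyclic": ["F", "W", "Y", "H", "P"],
    "glycine": ["G"]
  }
}
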