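# Expanded newborn screening indicator panel: 43 directly measured markers
# (11 amino acids, succinylacetone, 31 acylcarnitine channels) and 31 derived
# ratios, with laboratory reference ("cut-off") ranges in umol/L (ratios are
# dimensionless).  Combined channels such as "C3DC + C4OH" are single measured
# quantities reported jointly by non-derivatized MS/MS kits; they are never
# synthesized by addition.  Ratio markers are always derived from the measured
# channels via the formula given by their name.
markers:
  - {name: "C0",                 kind: raw,      low: 9,     high: 50}
  - {name: "C2",                 kind: raw,      low: 3,     high: 48}
  - {name: "C3",                 kind: raw,      low: 0.35,  high: 4.0}
  - {name: "C3DC + C4OH",        kind: combined, low: 0.03,  high: 0.4}
  - {name: "C4",                 kind: raw,      low: 0.1,   high: 0.5}
  - {name: "C4DC + C5OH",        kind: combined, low: 0.07,  high: 0.4}
  - {name: "C5",                 kind: raw,      low: 0.03,  high: 0.3}
  - {name: "C5:1",               kind: raw,      low: 0,     high: 0.03}
  - {name: "C5DC + C6OH",        kind: combined, low: 0.03,  high: 0.25}
  - {name: "C6",                 kind: raw,      low: 0.01,  high: 0.11}
  - {name: "C6DC",               kind: raw,      low: 0.03,  high: 0.27}
  - {name: "C8",                 kind: raw,      low: 0.02,  high: 0.2}
  - {name: "C8:1",               kind: raw,      low: 0.03,  high: 0.45}
  - {name: "C10:1",              kind: raw,      low: 0.02,  high: 0.17}
  - {name: "C10",                kind: raw,      low: 0.02,  high: 0.3}
  - {name: "C10:2",              kind: raw,      low: 0,     high: 0.15}
  - {name: "C12",                kind: raw,      low: 0.02,  high: 0.35}
  - {name: "C12:1",              kind: raw,      low: 0.01,  high: 0.37}
  - {name: "C14",                kind: raw,      low: 0.04,  high: 0.45}
  - {name: "C14:1",              kind: raw,      low: 0.02,  high: 0.35}
  - {name: "C14:2",              kind: raw,      low: 0,     high: 0.05}
  - {name: "C14OH",              kind: raw,      low: 0,     high: 0.05}
  - {name: "C16",                kind: raw,      low: 0.5,   high: 6.86}
  - {name: "C16:1",              kind: raw,      low: 0.02,  high: 0.5}
  - {name: "C16OH",              kind: raw,      low: 0,     high: 0.06}
  - {name: "C16:1OH",            kind: raw,      low: 0.01,  high: 0.08}
  - {name: "C18",                kind: raw,      low: 0.24,  high: 2}
  - {name: "C18:1",              kind: raw,      low: 0.38,  high: 3}
  - {name: "C18:2",              kind: raw,      low: 0.05,  high: 0.6}
  - {name: "C18OH",              kind: raw,      low: 0,     high: 0.03}
  - {name: "C18:1OH",            kind: raw,      low: 0,     high: 0.06}
  - {name: "ALA",                kind: raw,      low: 125,   high: 650}
  - {name: "ARG",                kind: raw,      low: 1,     high: 45}
  - {name: "CIT",                kind: raw,      low: 5.5,   high: 26}
  - {name: "GLY",                kind: raw,      low: 190,   high: 1000}
  - {name: "LEU + ILE + PRO-OH", kind: combined, low: 50,    high: 260}
  - {name: "MET",                kind: raw,      low: 6.5,   high: 40}
  - {name: "ORN",                kind: raw,      low: 30,    high: 250}
  - {name: "PHE",                kind: raw,      low: 23,    high: 100}
  - {name: "PRO",                kind: raw,      low: 75,    high: 420}
  - {name: "SA",                 kind: raw,      low: 0,     high: 1.6}
  - {name: "TYR",                kind: raw,      low: 30,    high: 250}
  - {name: "VAL",                kind: raw,      low: 40,    high: 230}
  - {name: "ARG/PHE",            kind: ratio,    low: 0.02,  high: 0.7}
  - {name: "(C4DC + C5OH)/C0",   kind: ratio,    low: 0,     high: 0.03}
  - {name: "MET/PHE",            kind: ratio,    low: 0.1,   high: 0.6}
  - {name: "MET/CIT",            kind: ratio,    low: 0.51,  high: 4}
  - {name: "ORN/CIT",            kind: ratio,    low: 2.5,   high: 22}
  - {name: "ARG/ORN",            kind: ratio,    low: 0.01,  high: 0.4}
  - {name: "ALA/CIT",            kind: ratio,    low: 9.5,   high: 65}
  - {name: "CIT/PHE",            kind: ratio,    low: 0.1,   high: 0.7}
  - {name: "PHE/TYR",            kind: ratio,    low: 0.2,   high: 1.4}
  - {name: "SA/PHE",             kind: ratio,    low: 0,     high: 0.04}
  - {name: "TYR/PHE",            kind: ratio,    low: 0.6,   high: 7}
  - {name: "(LEU + ILE + PRO-OH)/PHE", kind: ratio, low: 1.15, high: 5.2}
  - {name: "(LEU + ILE + PRO-OH)/TYR", kind: ratio, low: 0.5,  high: 4.2}
  - {name: "C0/(C16 + C18)",     kind: ratio,    low: 1.8,   high: 30}
  - {name: "C3/C0",              kind: ratio,    low: 0.01,  high: 0.2}
  - {name: "C3/C2",              kind: ratio,    low: 0.03,  high: 0.2}
  - {name: "C3/MET",             kind: ratio,    low: 0.02,  high: 0.3}
  - {name: "C4/C2",              kind: ratio,    low: 0,     high: 0.04}
  - {name: "C4/C3",              kind: ratio,    low: 0.04,  high: 0.45}
  - {name: "C5/C0",              kind: ratio,    low: 0,     high: 0.02}
  - {name: "C8/C2",              kind: ratio,    low: 0,     high: 0.01}
  - {name: "C8/C10",             kind: ratio,    low: 0.3,   high: 1.5}
  - {name: "C14:1/C2",           kind: ratio,    low: 0,     high: 0.02}
  - {name: "C14:1/C16",          kind: ratio,    low: 0.01,  high: 0.1}
  - {name: "C16OH/C16",          kind: ratio,    low: 0,     high: 0.02}
  - {name: "(C16 + C18:1)/C2",   kind: ratio,    low: 0.12,  high: 0.55}
  - {name: "(C3DC + C4OH)/C10",  kind: ratio,    low: 0.35,  high: 4.33}
  - {name: "(C5DC + C6OH)/(C3DC + C4OH)", kind: ratio, low: 0.3,  high: 2}
  - {name: "(C5DC + C6OH)/(C4DC + C5OH)", kind: ratio, low: 0.15, high: 1.6}
  - {name: "(C0 + C2 + C3 + C16 + C18:1 + C18)/CIT", kind: ratio, low: 1.3, high: 12}
  - {name: "(C4DC + C5OH)/C8",   kind: ratio,    low: 1,     high: 12}
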