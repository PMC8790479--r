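# Positive rules of the expanded newborn-screening panel.  Each entry screens
# for one disorder or a group of disorders sharing a biochemical signature
# (differential diagnosis is confirmatory, not screening; the flag carries all
# OMIM codes of the row).  `groups` is a disjunction of rule groups; the
# conditions inside one group are a conjunction.  Comparators are preserved
# exactly as the laboratory defines them (>, >=, <, <=); a value exactly at a
# strict threshold does not satisfy the condition.  Concentrations in umol/L.
rules:
  - id: HPA
    name: "Phenylalanine hydroxylase deficiency / tetrahydrobiopterin deficiency (hyperphenylalaninemia)"
    omim: ["261600", "233910", "261640", "612716", "264070", "261630"]
    category: AAMD
    groups:
      - ["PHE > 100", "PHE/TYR >= 1.4"]
      - ["PHE > 120"]
      - ["PHE/TYR >= 2.4"]
  - id: GA1
    name: "Glutaric acidemia type I"
    omim: ["231670"]
    category: OAMD
    groups:
      - ["C5DC + C6OH > 0.25", "(C5DC + C6OH)/(C3DC + C4OH) >= 2", "(C5DC + C6OH)/(C4DC + C5OH) > 1.6"]
      - ["C5DC + C6OH > 0.3"]
  - id: HHH
    name: "Hyperornithinemia-hyperammonemia-homocitrullinuria syndrome"
    omim: ["238970"]
    category: AAMD
    groups:
      - ["ORN > 196", "ORN/CIT > 22"]
      - ["ORN > 350"]
  - id: CIT_CD
    name: "Citrullinemia type I / citrin deficiency / argininosuccinic aciduria"
    omim: ["215700", "605814", "603471", "207900"]
    category: AAMD
    groups:
      - ["CIT > 26", "ALA/CIT < 9.5"]
      - ["CIT > 65"]
  - id: UCD
    name: "Carbamoylphosphate synthetase I / ornithine aminotransferase / ornithine transcarbamylase deficiency"
    omim: ["237300", "258870", "311250"]
    category: AAMD
    groups:
      - ["CIT < 5.5", "CIT/PHE < 0.1"]
      - ["CIT < 4.5"]
  - id: TYR1
    name: "Tyrosinemia type I"
    omim: ["276700"]
    category: AAMD
    groups:
      - ["SA > 1.1", "SA/PHE >= 0.04"]
      - ["SA > 1.8"]
  - id: MET_HCY
    name: "Homocystinuria / hypermethioninemia"
    omim: ["236200", "250850"]
    category: AAMD
    groups:
      - ["MET > 40", "MET/PHE > 0.6"]
      - ["MET > 65"]
  - id: MSUD
    name: "Maple syrup urine disease"
    omim: ["248600"]
    category: AAMD
    groups:
      - ["LEU + ILE + PRO-OH > 260", "(LEU + ILE + PRO-OH)/PHE > 5.2", "VAL > 230"]
      - ["LEU + ILE + PRO-OH > 400"]
  - id: TYR23
    name: "Tyrosinemia type II / tyrosinemia type III"
    omim: ["276600", "276710"]
    category: AAMD
    groups:
      - ["TYR > 250", "(LEU + ILE + PRO-OH)/TYR < 0.5", "PHE/TYR < 0.2"]
      - ["TYR > 400"]
  - id: ARG
    name: "Argininemia"
    omim: ["207800"]
    category: AAMD
    groups:
      - ["ARG/PHE > 0.7", "ARG/ORN > 0.4", "ARG > 45"]
      - ["ARG > 65"]
  - id: MMA_PA
    name: "Methylmalonic acidemia / propionic acidemia"
    omim: ["251000", "277400", "277410", "251100", "251110", "277380", "309541", "613646", "614265", "614857", "606054"]
    category: OAMD
    groups:
      - ["C3 > 4.5", "C3/C2 > 0.2"]
      - ["C3 > 6.5"]
      - ["C3/C0 > 0.3"]
      - ["C3/C2 > 0.29"]
      - ["C3/MET > 0.4"]
  - id: IVA_2MBD
    name: "Isovaleric acidemia / 2-methylbutyryl-CoA dehydrogenase deficiency"
    omim: ["243500", "610006"]
    category: OAMD
    groups:
      - ["C5 > 0.3", "C5/C0 >= 0.02"]
      - ["C5 > 0.8"]
  - id: MCC_HCS
    name: "Holocarboxylase synthetase / 3-methylglutaconyl-CoA hydratase / 3-methylcrotonyl-CoA carboxylase / HMG-CoA lyase deficiency"
    omim: ["253270", "250950", "210200", "210210", "246450"]
    category: OAMD
    groups:
      - ["C4DC + C5OH > 0.4", "(C4DC + C5OH)/C0 >= 0.03"]
      - ["C4DC + C5OH > 0.5"]
  - id: MADD
    name: "Multiple acyl-CoA dehydrogenase deficiency"
    omim: ["231680"]
    category: FAOD
    groups:
      - ["C5 > 0.3", "C4 > 0.5"]
  - id: BKT
    name: "Beta-ketothiolase deficiency"
    omim: ["203750"]
    category: OAMD
    groups:
      - ["C5:1 >= 0.01", "C4DC + C5OH > 0.4"]
  - id: MAL
    name: "Malonic acidemia"
    omim: ["248360"]
    category: OAMD
    groups:
      - ["C3DC + C4OH > 0.4", "(C3DC + C4OH)/C10 > 4.33"]
      - ["C3DC + C4OH > 0.8"]
  - id: MCADD
    name: "Medium-chain acyl-CoA dehydrogenase deficiency"
    omim: ["201450"]
    category: FAOD
    groups:
      - ["C6 > 0.11", "C8 > 0.2", "C8/C2 >= 0.01", "(C4DC + C5OH)/C8 <= 1"]
      - ["C8 > 0.3"]
  - id: VLCADD
    name: "Very-long-chain acyl-CoA dehydrogenase deficiency"
    omim: ["201475"]
    category: FAOD
    groups:
      - ["C14:1 > 0.35", "C14:1/C16 > 0.1", "C14:1/C2 >= 0.02"]
      - ["C14:1 > 0.5"]
  - id: LCHAD_TFP
    name: "Long-chain 3-hydroxyacyl-CoA dehydrogenase / trifunctional protein deficiency"
    omim: ["609016", "609015"]
    category: FAOD
    groups:
      - ["C16OH > 0.06", "C16OH/C16 >= 0.02", "C18:1OH > 0.04", "C18OH > 0.03"]
  - id: PCD
    name: "Primary carnitine deficiency"
    omim: ["212140"]
    category: FAOD
    groups:
      - ["C0 < 8.5"]
      - ["C0 < 9.0", "(C0 + C2 + C3 + C16 + C18:1 + C18)/CIT <= 1.3"]
  - id: CPT1
    name: "Carnitine palmitoyltransferase I deficiency"
    omim: ["255120"]
    category: FAOD
    groups:
      - ["C0/(C16 + C18) > 30", "C0 > 50", "(C16 + C18:1)/C2 < 0.12"]
      - ["C0 > 100"]
  - id: CPT2_CACT
    name: "Carnitine palmitoyltransferase II / carnitine-acylcarnitine translocase deficiency"
    omim: ["255110", "608836", "600649", "212138"]
    category: FAOD
    groups:
      - ["(C16 + C18:1)/C2 > 0.55", "C16 > 6.86", "C0/(C16 + C18) <= 1.8"]
  - id: SCADD
    name: "Short-chain acyl-CoA dehydrogenase deficiency"
    omim: ["201470"]
    category: FAOD
    groups:
      - ["C4 > 0.5", "C4/C2 > 0.04"]
      - ["C4 > 0.8"]
  - id: HPRO
    name: "Hyperprolinemia"
    omim: ["239500"]
    category: AAMD
    groups:
      - ["PRO > 340"]
  - id: NKH
    name: "Nonketotic hyperglycinemia"
    omim: ["617301", "605899"]
    category: AAMD
    groups:
      - ["GLY > 1000"]
  - id: IBD_EE
    name: "Isobutyryl-CoA dehydrogenase deficiency / ethylmalonic encephalopathy"
    omim: ["611283", "602473"]
    category: OAMD
    groups:
      - ["C4/C3 > 0.45", "C4/C2 > 0.04"]
      - ["C4 > 0.8"]
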