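[{"name":"erlotinib","targets":[{"node":"EGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"EGFR tyrosine kinase inhibitor; alignment drug"},{"name":"lapatinib","targets":[{"node":"EGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"ERBB2","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"dual EGFR/ERBB2 (HER2) kinase inhibitor"},{"name":"BIBW2992","targets":[{"node":"EGFR","action":"inhibit","potency":1,"emax":0.99,"hill_n":1},{"node":"ERBB2","action":"inhibit","potency":1,"emax":0.99,"hill_n":1}],"aliases":["afatinib"],"note":"irreversible EGFR/ERBB2 inhibitor; modeled reversible with high Emax"},{"name":"AZD6244","targets":[{"node":"MEK","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":["AZD2644","selumetinib"],"note":"MEK1/2 inhibitor"},{"name":"sorafenib","targets":[{"node":"BRAF","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"VEGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"PDGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"multi-kinase RAF/VEGFR/PDGFR inhibitor; alignment drug"},{"name":"dasatinib","targets":[{"node":"SRC","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"ABL","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"SRC/ABL inhibitor; alignment drug"},{"name":"nilotinib","targets":[{"node":"ABL","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"KIT","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"PDGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"ABL/KIT/PDGFR inhibitor"},{"name":"imatinib","targets":[{"node":"ABL","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"KIT","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"PDGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"ABL/KIT/PDGFR inhibitor"},{"name":"sunitinib","targets":[{"node":"VEGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"PDGFR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1},{"node":"KIT","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"multi-RTK inhibitor"},{"name":"PD0332991","targets":[{"node":"CDK4_CCND1","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":["palbociclib"],"note":"CDK4/6-cyclin D1 inhibitor (blocks active complex formation)"},{"name":"bortezomib","targets":[{"node":"PSM","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"proteasome inhibitor (stabilizes IkB, NOXA, p53)"},{"name":"everolimus","targets":[{"node":"MTOR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"mTORC1 inhibitor"},{"name":"celecoxib","targets":[{"node":"COX2","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"COX2 inhibitor"},{"name":"pitavastatin","targets":[{"node":"HMGCR","action":"inhibit","potency":1,"emax":0.95,"hill_n":1}],"aliases":[],"note":"HMG-CoA reductase inhibitor (blocks mevalonate-dependent RAS prenylation)"}]
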