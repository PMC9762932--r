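{
  "name": "genomics_england",
  "genes": ["ALS2", "ANG", "ANXA11", "ATXN2", "C9orf72", "CHCHD10", "DCTN1", "ERBB4", "FIG4", "FUS", "HNRNPA1", "MATR3", "NEFH", "OPTN", "PFN1", "SETX", "SIGMAR1", "SOD1", "SPG11", "SQSTM1", "TARDBP", "TBK1", "TUB4A", "UBQLN2", "VAPB", "VCP"],
  "biallelic_only": "ALS2"
}
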