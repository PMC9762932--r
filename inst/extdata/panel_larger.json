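{
  "name": "larger",
  "genes": ["ANG", "ATXN2", "C21orf2", "C9orf72", "CHCHD10", "DAO", "DCTN1", "FUS", "HNRNPA1", "MATR3", "MOBP", "NEK1", "OPTN", "PFN1", "SCFD1", "SOD1", "SQSTM1", "TAF15", "TARDBP", "TBK1", "TUB4A", "UBQLN2", "VAPB", "VCP"],
  "biallelic_only": []
}
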