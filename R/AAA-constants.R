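# Single-letter <-> three-letter amino-acid tables used throughout.
.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA3 <- stats::setNames(names(.AA1), .AA1)
.AA_LETTERS <- unname(.AA1)

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
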