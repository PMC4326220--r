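# Write minimal PDB-format text by hand (independent of bio3d's writer).
pdbAtomLine <- function(serial, name, resid, chain, resno, x, y, z,
                        alt = " ", occ = 1.0, element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, resid, chain, resno, x, y, z,
          occ, 0.0, element)
}

writePdbText <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

threeResiduePdb <- function() {
  lines <- c(
    pdbAtomLine(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, element = "C"),
    pdbAtomLine(3, "C",  "ALA", "A", 1, 2.0, 1.4, 0.0),
    pdbAtomLine(4, "N",  "GLY", "A", 2, 3.3, 1.5, 0.0),
    pdbAtomLine(5, "CA", "GLY", "A", 2, 4.5, 2.3, 0.0, element = "C"),
    pdbAtomLine(6, "C",  "GLY", "A", 2, 5.9, 1.7, 0.0),
    pdbAtomLine(7, "N",  "SER", "A", 3, 7.0, 2.5, 0.0),
    pdbAtomLine(8, "CA", "SER", "A", 3, 8.4, 2.1, 0.0, element = "C"),
    pdbAtomLine(9, "C",  "SER", "A", 3, 9.5, 3.2, 0.0))
  writePdbText(lines)
}
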