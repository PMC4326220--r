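test_that("readPdb parses a small chain, maps residues, and enforces errors", {
  path <- threeResiduePdb()
  ag <- readPdb(path, "A")
  expect_s4_class(ag, "AntigenStructure")
  expect_equal(nrow(residueTable(ag)), 3)
  expect_equal(paste(residueTable(ag)$aa, collapse = ""), "AGS")

  expect_error(readPdb(path, "Z"), "chain not found")
  expect_error(readPdb(tempfile(), "A"), "cannot read")
})

test_that("altloc policy keeps exactly one atom, the highest occupancy", {
  lines <- c(
    pdbAtomLine(1, "N",  "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 1.5, 0, 0, element = "C"),
    pdbAtomLine(3, "CB", "ALA", "A", 1, 2.0, 1.0, 0, alt = "A",
                occ = 0.4, element = "C"),
    pdbAtomLine(4, "CB", "ALA", "A", 1, 2.0, -1.0, 0, alt = "B",
                occ = 0.6, element = "C"))
  ag <- readPdb(writePdbText(lines), "A")
  cb <- ag@atoms[ag@atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$y, -1.0)  # the 0.6-occupancy altloc
})

test_that("waters, hetero records and hydrogens are excluded", {
  lines <- c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
    pdbAtomLine(2, "H",  "ALA", "A", 1, 0.5, 0.5, 0, element = "H"),
    sub("^ATOM  ", "HETATM", pdbAtomLine(3, "FE", "HEM", "A", 90, 9, 9, 9,
                                         element = "FE")),
    pdbAtomLine(4, "O", "HOH", "A", 101, 5, 5, 5))
  ag <- readPdb(writePdbText(lines), "A")
  expect_equal(nrow(ag@atoms), 1)
  expect_equal(ag@atoms$elety, "CA")
})

test_that("isolated and non-overlapping atoms give the closed-form ASA", {
  # a single carbon: ASA = 4*pi*(1.7 + 1.4)^2
  one <- makeStructure(data.frame(resno = 1, aa = "A"),
                       data.frame(resno = 1, elety = "CA", element = "C",
                                  x = 0, y = 0, z = 0, sidechain = FALSE))
  one <- computeASA(one)
  expect_equal(residueTable(one)$asa_total, 4 * pi * 3.1^2,
               tolerance = 0.01)

  # two identical atoms far apart: each isolated
  two <- makeStructure(data.frame(resno = 1:2, aa = c("A", "A")),
                       data.frame(resno = 1:2, elety = "CA", element = "C",
                                  x = c(0, 50), y = 0, z = 0,
                                  sidechain = FALSE))
  two <- computeASA(two)
  expect_equal(residueTable(two)$asa_total, rep(4 * pi * 3.1^2, 2),
               tolerance = 0.01)

  # two coincident spheres: the union equals one sphere
  co <- makeStructure(data.frame(resno = 1:2, aa = c("A", "A")),
                      data.frame(resno = 1:2, elety = "CA", element = "C",
                                 x = c(0, 0), y = 0, z = 0,
                                 sidechain = FALSE))
  co <- computeASA(co)
  expect_equal(sum(residueTable(co)$asa_total), 4 * pi * 3.1^2,
               tolerance = 0.01)
})

test_that("sphere sampling is converged: n vs 4n within 2 percent", {
  ag <- makeLinearStructure(c("A", "K", "W", "G", "S"), spacing = 4)
  a1 <- residueTable(computeASA(ag, nPoints = 960))$asa_total
  a2 <- residueTable(computeASA(ag, nPoints = 3840))$asa_total
  expect_true(all(abs(a1 - a2) / a2 < 0.02))
})

test_that("extractSurface applies the side-chain RSA threshold", {
  ag <- makeLinearStructure(c("A", "K", "W", "S"), spacing = 8)
  surf <- extractSurface(ag)
  expect_equal(length(surfaceResidues(surf)), 4)  # fully exposed chain

  # raising the threshold to 1.0 empties the surface (reference scale set
  # to the full isolated-atom sphere so RSA is a true fraction here)
  ref <- data.frame(aa = c("A", "K", "W", "S"), total = 242,
                    sidechain = 4 * pi * 3.1^2)
  expect_gt(length(surfaceResidues(extractSurface(ag, 0.05,
                                                  reference = ref))), 0)
  expect_equal(length(surfaceResidues(extractSurface(ag, 1.0,
                                                     reference = ref))), 0)

  # a residue caged by dummy atoms is buried
  shell <- as.matrix(expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3),
                                 z = c(-3, 0, 3)))
  shell <- shell[rowSums(shell^2) > 0, ]
  residues <- data.frame(resno = 1:2, aa = c("A", "K"))
  atoms <- rbind(
    data.frame(resno = 1, elety = "CA", element = "C", x = 0, y = 0, z = 0,
               sidechain = FALSE),
    data.frame(resno = 1, elety = "CB", element = "C", x = 0, y = 0, z = 0,
               sidechain = TRUE),
    data.frame(resno = 2, elety = "CG", element = "C", x = shell[, 1],
               y = shell[, 2], z = shell[, 3], sidechain = TRUE))
  caged <- makeStructure(residues, atoms)
  surf2 <- extractSurface(caged)
  expect_false(residueKey("A", 1, "") %in% surfaceResidues(surf2))
})

test_that("surface sets are nested as the threshold rises", {
  case <- syntheticAntigen(nResidues = 30, fold = "blob", epitopeSize = 5,
                           seed = 7)
  s1 <- surfaceResidues(extractSurface(case$structure, 0.02))
  s2 <- surfaceResidues(extractSurface(case$structure, 0.10))
  s3 <- surfaceResidues(extractSurface(case$structure, 0.30))
  expect_true(all(s2 %in% s1))
  expect_true(all(s3 %in% s2))
})

test_that("adding partner chains never increases residue ASA", {
  case <- syntheticAntigen(nResidues = 20, fold = "helix", epitopeSize = 5,
                           seed = 3)
  ag <- case$structure
  # bolt a partner blob next to the first epitope residue
  tab <- residueTable(case$surface)
  epi1 <- tab[tab$key == case$epitope[1], ]
  partner <- data.frame(chain = "P", resno = 1, insert = "", resid = "ALA",
                        elety = "CA", element = "C",
                        x = epi1$ca_x + 3, y = epi1$ca_y, z = epi1$ca_z,
                        sidechain = FALSE)
  ag@partnerChains <- "P"
  ag@atoms <- rbind(ag@atoms, partner)
  alone <- residueTable(computeASA(ag, chains = "A"))$asa_total
  complexed <- residueTable(computeASA(ag, chains = c("A", "P")))$asa_total
  expect_true(all(complexed <= alone + 1e-9))
})

test_that("epitope annotation flags ASA loss above the threshold only", {
  ag <- makeLinearStructure(c("A", "K", "W", "S", "E"), spacing = 8)

  # partner far away: no epitope
  far <- data.frame(chain = "H", resno = 1, insert = "", resid = "GLY",
                    elety = "CA", element = "C", x = 500, y = 500, z = 500,
                    sidechain = FALSE)
  agFar <- ag
  agFar@partnerChains <- "H"
  agFar@atoms <- rbind(ag@atoms, far)
  expect_length(epitopeResidues(annotateEpitope(agFar)), 0)

  # partner sphere pressed onto residue 3's side chain: only that residue
  near <- far
  near$x <- 16; near$y <- 5.5; near$z <- 0  # just above residue 3's CB
  agNear <- ag
  agNear@partnerChains <- "H"
  agNear@atoms <- rbind(ag@atoms, near)
  surf <- annotateEpitope(agNear)
  expect_equal(epitopeResidues(surf), residueKey("A", 3, ""))

  # an absurd threshold empties the annotation
  expect_length(epitopeResidues(annotateEpitope(agNear, 1e6)), 0)

  # no partners at all is an error
  expect_error(annotateEpitope(ag), "without binding partner")
})

test_that("residue lists parse in both dialects and round-trip", {
  five <- parseResidueList("F17 Y21 Y45 K48 Q79")
  expect_equal(nrow(five), 5)
  expect_equal(five$resno, c(17L, 21L, 45L, 48L, 79L))

  numFirst <- parseResidueList("20V 27H 28P")
  expect_equal(numFirst$aa, c("V", "H", "P"))
  expect_equal(numFirst$resno, c(20L, 27L, 28L))

  expect_equal(nrow(parseResidueList("")), 0)
  expect_error(parseResidueList("I80 80I"), "duplicate")
  expect_error(parseResidueList("I80 Z!9"), "malformed residue token: Z!9")

  # formatter inverse on generated lists
  set.seed(42)
  for (i in 1:10) {
    n <- sample(1:20, 1)
    df <- data.frame(resno = sample(1:500, n),
                     aa = sample(mimoprune:::.AA_LETTERS, n, replace = TRUE))
    expect_equal(parseResidueList(formatResidueList(df)), df,
                 ignore_attr = TRUE)
  }
})
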