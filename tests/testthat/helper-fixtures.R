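# Fixtures are built in code: tiny structures assembled directly from atom
# tables, PDB text written on the fly, and an exhaustive path-alignment
# oracle kept independent of the package's search kernel.

# Build an AntigenStructure straight from a per-residue atom list.
# residues: data.frame(resno, aa) ; atoms: data.frame(resno, elety, element,
# x, y, z, sidechain)
makeStructure <- function(residues, atoms, chain = "A", pdbId = "FIX",
                          probeRadius = 1.4) {
  aa3 <- setNames(names(mimoprune:::.AA1), mimoprune:::.AA1)
  at <- data.frame(chain = chain, resno = atoms$resno, insert = "",
                   resid = unname(aa3[residues$aa[match(atoms$resno,
                                                        residues$resno)]]),
                   elety = atoms$elety, element = atoms$element,
                   x = atoms$x, y = atoms$y, z = atoms$z,
                   sidechain = atoms$sidechain, stringsAsFactors = FALSE)
  at$resid[is.na(at$resid)] <- "UNK"
  res <- data.frame(key = residueKey(chain, residues$resno, ""),
                    chain = chain, resno = residues$resno, insert = "",
                    aa = residues$aa, asa_total = NA_real_,
                    asa_sidechain = NA_real_, stringsAsFactors = FALSE)
  new("AntigenStructure", pdbId = pdbId, antigenChain = chain,
      partnerChains = character(0), atoms = at, residues = res,
      probeRadius = probeRadius)
}

# A chain of CA+CB residues along the x axis, all fully exposed.
makeLinearStructure <- function(aa, spacing = 6, chain = "A") {
  n <- length(aa)
  residues <- data.frame(resno = seq_len(n), aa = aa)
  atoms <- rbind(
    data.frame(resno = seq_len(n), elety = "CA", element = "C",
               x = spacing * (seq_len(n) - 1), y = 0, z = 0,
               sidechain = FALSE),
    data.frame(resno = seq_len(n), elety = "CB", element = "C",
               x = spacing * (seq_len(n) - 1), y = 3, z = 0,
               sidechain = TRUE))
  makeStructure(residues, atoms, chain = chain)
}

# A SurfaceSet built directly from residue keys, amino acids and CA coords
# (no ASA computation): enough for feature/patch/alignment fixtures.
makeSurface <- function(aa, coords, chain = "A", structure = NULL) {
  n <- length(aa)
  coords <- matrix(coords, ncol = 3)
  if (is.null(structure)) {
    residues <- data.frame(resno = seq_len(n), aa = aa)
    atoms <- data.frame(resno = seq_len(n), elety = "CA", element = "C",
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        sidechain = FALSE)
    structure <- makeStructure(residues, atoms, chain = chain)
  }
  keys <- residueKey(chain, seq_len(n), "")
  tab <- data.frame(key = keys, chain = chain, resno = seq_len(n),
                    insert = "", aa = aa, asa_total = 100,
                    asa_sidechain = 50, rsa_sidechain = 0.5,
                    is_surface = TRUE, is_epitope = FALSE,
                    ca_x = coords[, 1], ca_y = coords[, 2],
                    ca_z = coords[, 3], stringsAsFactors = FALSE)
  new("SurfaceSet", structure = structure, table = tab, residues = keys,
      rsaThreshold = 0.05, epitope = character(0), flags = character(0))
}

# A PatchGraph that is a simple path spelling the given amino acids.
makePathGraph <- function(aa, chain = "A") {
  n <- length(aa)
  keys <- residueKey(chain, seq_len(n), "")
  edges <- if (n > 1) cbind(seq_len(n - 1), 2:n) else
    matrix(integer(0), 0, 2)
  coords <- cbind(5 * seq_len(n), 0, 0)
  rownames(coords) <- keys
  new("PatchGraph", center = keys[1], members = keys, aa = aa,
      coords = coords, edges = matrix(as.integer(edges), ncol = 2),
      adt = 5, cf = if (n > 1) nrow(edges) / choose(n, 2) else 1,
      flags = character(0))
}

# A PatchGraph from an explicit edge list over given amino acids.
makeGraph <- function(aa, edges, chain = "A") {
  n <- length(aa)
  keys <- residueKey(chain, seq_len(n), "")
  coords <- cbind(seq_len(n), 0, 0)
  rownames(coords) <- keys
  edges <- matrix(as.integer(edges), ncol = 2)
  new("PatchGraph", center = keys[1], members = keys, aa = aa,
      coords = coords, edges = edges, adt = 1,
      cf = if (n > 1) nrow(edges) / choose(n, 2) else 1,
      flags = character(0))
}

# Identity-like substitution matrix over the 20 amino acids.
identityMatrix <- function(match = 1, mismatch = 0) {
  letters <- mimoprune:::.AA_LETTERS
  m <- matrix(mismatch, 20, 20, dimnames = list(letters, letters))
  diag(m) <- match
  m
}

# --- independent oracle: exhaustive enumeration over (skip set, simple
# path) pairs, mirroring the alignment semantics with no pruning ----------
oracleAlign <- function(aa, edges, peptide, matrix, gap, maxSkips) {
  n <- length(aa)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
  }
  pep <- strsplit(peptide, "")[[1]]
  L <- length(pep)
  best <- list(score = -Inf, found = FALSE, nodes = 0L)
  rec <- function(p, path, skips, score) {
    best$nodes <<- best$nodes + 1L
    if (p > L) {
      if (length(path) > 0 && score > best$score) {
        best$score <<- score
        best$found <<- TRUE
      }
      return(invisible())
    }
    if (skips < maxSkips)
      rec(p + 1, path, skips + 1, score + gap)
    cand <- if (length(path) == 0) seq_len(n) else
      setdiff(adj[[path[length(path)]]], path)
    for (v in cand)
      rec(p + 1, c(path, v), skips, score + matrix[pep[p], aa[v]])
    invisible()
  }
  rec(1, integer(0), 0, 0)
  best
}

# Random connected-ish graph fixture for the oracle comparison.
randomGraphFixture <- function(nV, pEdge, rng) {
  aa <- sample(mimoprune:::.AA_LETTERS, nV, replace = TRUE)
  pairs <- which(upper.tri(matrix(0, nV, nV)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < pEdge
  # always keep a spanning path so the graph is connected
  edges <- unique(rbind(cbind(seq_len(nV - 1), 2:nV),
                        pairs[keep, , drop = FALSE]))
  list(aa = aa, edges = matrix(as.integer(edges), ncol = 2))
}
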