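#' Read an antigen (and optional partner chains) from a PDB file
#'
#' Parses ATOM records via \pkg{bio3d}, keeping the first NMR model only.
#' Waters and hetero records are excluded, hydrogens are dropped, and where
#' alternate locations exist the highest-occupancy one (first on ties) is
#' kept. Residues with a non-standard name are carried with amino acid
#' \code{"X"}. Author numbering and insertion codes are preserved.
#'
#' @param path path to a PDB-format file.
#' @param antigenChain chain identifier of the antigen (must occur in file).
#' @param partnerChains optional character vector of antibody/ligand chains
#'   used for epitope annotation.
#' @param pdbId identifier stored on the object; defaults to the file stem.
#' @param probeRadius solvent probe radius in Angstrom.
#' @return an \linkS4class{AntigenStructure}.
#' @examples
#' pdb <- writePdb(syntheticAntigen(nResidues = 10, seed = 1)$structure,
#'                 tempfile(fileext = ".pdb"))
#' readPdb(pdb, "A")
#' @export
readPdb <- function(path, antigenChain, partnerChains = NULL,
                    pdbId = NULL, probeRadius = 1.4) {
  if (!file.exists(path))
    stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  chains <- c(antigenChain, partnerChains)
  if (!(antigenChain %in% at$chain))
    stop("chain not found: ", antigenChain)
  missing_partners <- setdiff(partnerChains, unique(at$chain))
  if (length(missing_partners))
    stop("chain not found: ", paste(missing_partners, collapse = ", "))
  at <- at[at$chain %in% chains, , drop = FALSE]

  # element symbol: prefer the PDB element column, fall back to atom name
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9]", "", trimws(at$elety[bad])), 1, 1)
  at$element <- elem
  at <- at[at$element != "H", , drop = FALSE]

  # altloc policy: per atom position keep highest occupancy, first on tie
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  pos <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(pos, unique(pos))),
                        function(i) i[which.max(occ[i])]), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = trimws(at$elety), element = at$element,
    x = at$x, y = at$y, z = at$z,
    sidechain = !(trimws(at$elety) %in% .BACKBONE_ATOMS),
    stringsAsFactors = FALSE)

  ag <- atoms[atoms$chain == antigenChain, , drop = FALSE]
  rid <- paste(ag$resno, ag$insert, sep = "|")
  first <- !duplicated(rid)
  if (nrow(ag) == 0L)
    stop("empty antigen chain")
  aa <- .AA1[ag$resid[first]]
  aa[is.na(aa)] <- "X"
  residues <- data.frame(
    key = residueKey(antigenChain, ag$resno[first], ag$insert[first]),
    chain = antigenChain, resno = ag$resno[first], insert = ag$insert[first],
    aa = unname(aa), asa_total = NA_real_, asa_sidechain = NA_real_,
    stringsAsFactors = FALSE)
  if (nrow(residues) == 0L)
    stop("empty antigen chain")

  new("AntigenStructure",
      pdbId = if (is.null(pdbId)) sub("\\.pdb$", "", basename(path)) else pdbId,
      antigenChain = antigenChain,
      partnerChains = as.character(partnerChains %||% character(0)),
      atoms = atoms, residues = residues, probeRadius = probeRadius)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an AntigenStructure to a PDB file
#'
#' Emits standard ATOM records (antigen chain first, then partners) that
#' round-trip through \code{\link{readPdb}} losslessly at residue level.
#'
#' @param structure an \linkS4class{AntigenStructure}.
#' @param path output file path.
#' @return \code{path}, invisibly... returned visibly for convenience.
#' @export
writePdb <- function(structure, path) {
  at <- structure@atoms
  ord <- order(match(at$chain, c(structure@antigenChain,
                                 structure@partnerChains)),
               at$resno, at$insert)
  at <- at[ord, , drop = FALSE]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid, insert = at$insert,
                   chain = at$chain, elety = at$elety,
                   eleno = seq_len(nrow(at)), o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)), elesy = at$element)
  path
}

#' Parse a residue-list string such as "I80 M81 R82" or "20V 27H"
#'
#' Accepts both dialects found in the epitope-mapping literature: amino-acid
#' letter before the author number and number before the letter. Tokens are
#' whitespace- and/or comma-separated; duplicates are rejected.
#'
#' @param text the residue-list string (may be empty).
#' @return data.frame with columns \code{resno} (integer) and \code{aa}
#'   (one-letter code), rows in input order.
#' @examples
#' parseResidueList("F17 Y21 Y45 K48 Q79")
#' parseResidueList("20V 27H 28P")
#' @export
parseResidueList <- function(text) {
  tokens <- strsplit(trimws(text), "[,[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    return(data.frame(resno = integer(0), aa = character(0)))
  aa_first <- grepl("^[A-Za-z][0-9]+$", tokens)
  num_first <- grepl("^[0-9]+[A-Za-z]$", tokens)
  bad <- !(aa_first | num_first)
  if (any(bad))
    stop("malformed residue token: ", tokens[which(bad)[1]])
  aa <- toupper(ifelse(aa_first,
                       substr(tokens, 1, 1),
                       substring(tokens, nchar(tokens))))
  resno <- as.integer(ifelse(aa_first,
                             substring(tokens, 2),
                             substr(tokens, 1, nchar(tokens) - 1L)))
  if (any(!aa %in% c(.AA_LETTERS, "X")))
    stop("malformed residue token: ",
         tokens[which(!aa %in% c(.AA_LETTERS, "X"))[1]])
  if (anyDuplicated(resno))
    stop("duplicate residue in list: ", resno[which(duplicated(resno))[1]])
  data.frame(resno = resno, aa = aa, stringsAsFactors = FALSE)
}

#' Format a residue list back to "I80 M81 ..." text
#'
#' Inverse of \code{\link{parseResidueList}} (letter-first dialect).
#'
#' @param residues data.frame with columns resno and aa.
#' @return single string.
#' @export
formatResidueList <- function(residues) {
  paste0(residues$aa, residues$resno, collapse = " ")
}
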