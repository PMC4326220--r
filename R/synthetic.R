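# Self-contained synthetic test inputs: toy antigen structures with planted
# epitopes, matching noisy mimotopes, and labelled feature tables with the
# training-data class imbalance (about eight nonepitopes per epitope).

#' Generate a toy antigen with a planted epitope
#'
#' Builds an ideal peptide backbone (N, CA, C) on the chosen fold with one
#' pseudo side-chain atom per residue placed 1.53 A along the outward normal
#' from the chain centroid, assigns a random sequence, and plants a
#' spatially contiguous epitope: the \code{epitopeSize} surface residues
#' nearest a randomly chosen anchor. Deterministic per seed.
#'
#' @param nResidues chain length.
#' @param fold "helix", "sheet" or "blob" (mixed dihedrals).
#' @param epitopeSize planted epitope size (<= surface count).
#' @param seed integer seed.
#' @param chain chain identifier.
#' @param rsaThreshold surface cutoff used when planting.
#' @return list with \code{structure} (\linkS4class{AntigenStructure}),
#'   \code{surface} (\linkS4class{SurfaceSet} with the planted epitope
#'   annotated) and \code{epitope} (keys).
#' @export
syntheticAntigen <- function(nResidues = 60,
                             fold = c("helix", "sheet", "blob"),
                             epitopeSize = 10, seed = 1, chain = "A",
                             rsaThreshold = 0.05) {
  fold <- match.arg(fold)
  stopifnot(epitopeSize <= nResidues, nResidues >= 1)
  set.seed(seed)
  angles <- switch(fold,
    helix = list(phi = rep(-57, nResidues), psi = rep(-47, nResidues)),
    sheet = list(phi = rep(-139, nResidues), psi = rep(135, nResidues)),
    blob = {
      k <- sample(c("H", "E", "C"), nResidues, replace = TRUE,
                  prob = c(0.4, 0.3, 0.3))
      list(phi = ifelse(k == "H", -57, ifelse(k == "E", -139, -75)) +
             runif(nResidues, -10, 10),
           psi = ifelse(k == "H", -47, ifelse(k == "E", 135, 150)) +
             runif(nResidues, -10, 10))
    })
  bb <- buildBackbone(angles$phi, angles$psi)
  centroid <- colMeans(bb$CA)
  cb <- t(vapply(seq_len(nResidues), function(i) {
    u <- bb$CA[i, ] - centroid
    n <- sqrt(sum(u^2))
    if (n < 1e-9) u <- c(0, 0, 1) else u <- u / n
    bb$CA[i, ] + 1.53 * u
  }, numeric(3)))
  aa <- sample(.AA_LETTERS, nResidues, replace = TRUE)
  resno <- seq_len(nResidues)
  mk <- function(xyz, elety, element, sidechain)
    data.frame(chain = chain, resno = resno, insert = "",
               resid = .AA3[aa], elety = elety, element = element,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               sidechain = sidechain, stringsAsFactors = FALSE)
  atoms <- rbind(mk(bb$N, "N", "N", FALSE), mk(bb$CA, "CA", "C", FALSE),
                 mk(bb$C, "C", "C", FALSE), mk(cb, "CB", "C", TRUE))
  atoms <- atoms[order(atoms$resno,
                       match(atoms$elety, c("N", "CA", "C", "CB"))), ]
  rownames(atoms) <- NULL
  residues <- data.frame(key = residueKey(chain, resno, ""), chain = chain,
                         resno = resno, insert = "", aa = aa,
                         asa_total = NA_real_, asa_sidechain = NA_real_,
                         stringsAsFactors = FALSE)
  structure <- new("AntigenStructure",
                   pdbId = paste0("SYN", fold, seed),
                   antigenChain = chain, partnerChains = character(0),
                   atoms = atoms, residues = residues, probeRadius = 1.4)
  surf <- extractSurface(structure, rsaThreshold = rsaThreshold)
  if (length(surf@residues) < epitopeSize)
    stop("epitope size ", epitopeSize, " exceeds achievable surface (",
         length(surf@residues), ")")
  coords <- .surfCoords(surf)
  anchor <- sample(seq_along(surf@residues), 1)
  d <- sqrt(rowSums(sweep(coords, 2, coords[anchor, ])^2))
  epi <- surf@residues[order(d)[seq_len(epitopeSize)]]
  tab <- surf@table
  tab$is_epitope <- tab$key %in% epi
  surface <- new("SurfaceSet", structure = structure, table = tab,
                 residues = surf@residues, rsaThreshold = rsaThreshold,
                 epitope = surf@residues[surf@residues %in% epi],
                 flags = c(surf@flags, "planted_epitope"))
  list(structure = structure, surface = surface, epitope = surface@epitope)
}

#' Generate mimotopes for a planted epitope
#'
#' Each peptide reads the amino acids along a random simple walk in the
#' adjacency graph of the planted epitope residues (smallest connected
#' distance threshold), then receives \code{noise} random substitutions —
#' emulating biopanning output. Deterministic per seed.
#'
#' @param case output of \code{\link{syntheticAntigen}}.
#' @param count number of peptides.
#' @param length peptide length (scalar or vector recycled over peptides).
#' @param noise substitutions per peptide (< length).
#' @param seed integer seed.
#' @param adtMax largest distance threshold tried when connecting the
#'   epitope graph, A.
#' @return an \link[Biostrings]{AAStringSet}.
#' @export
syntheticMimotopes <- function(case, count = 10, length = 6, noise = 1,
                               seed = 1, adtMax = 14) {
  stopifnot(all(noise < length))
  surface <- case$surface
  epi <- case$epitope
  lens <- rep_len(length, count)
  stopifnot(max(lens) <= base::length(epi))
  g <- buildPatchGraph(list(center = epi[1], members = epi), surface,
                       cfTarget = 0, adtMin = 4, adtMax = adtMax,
                       step = 0.5)
  adj <- lapply(seq_along(g@members), function(i) integer(0))
  for (e in seq_len(nrow(g@edges))) {
    u <- g@edges[e, 1]; v <- g@edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  aa <- g@aa
  set.seed(seed)
  # randomized depth-first path search with backtracking: finds a simple
  # path of the requested length whenever one exists
  findPath <- function(adjList, L) {
    dfs <- function(path) {
      if (base::length(path) == L) return(path)
      nxt <- setdiff(adjList[[path[base::length(path)]]], path)
      for (v in if (base::length(nxt) > 1) sample(nxt) else nxt) {
        got <- dfs(c(path, v))
        if (!is.null(got)) return(got)
      }
      NULL
    }
    for (s in sample(base::length(adjList))) {
      got <- dfs(s)
      if (!is.null(got)) return(got)
    }
    NULL
  }
  peps <- character(count)
  for (k in seq_len(count)) {
    L <- lens[k]
    walk <- findPath(adj, L)
    if (is.null(walk)) {
      # epitope graph too tree-like at this threshold: raise the floor of
      # the threshold search so the graph densifies, and retry
      for (extra in seq(2, 10, by = 2)) {
        g2 <- buildPatchGraph(list(center = epi[1], members = epi), surface,
                              cfTarget = 0, adtMin = 4 + extra,
                              adtMax = adtMax + extra, step = 0.5)
        adj2 <- lapply(seq_along(g2@members), function(i) integer(0))
        for (e in seq_len(nrow(g2@edges))) {
          u <- g2@edges[e, 1]; v <- g2@edges[e, 2]
          adj2[[u]] <- c(adj2[[u]], v)
          adj2[[v]] <- c(adj2[[v]], u)
        }
        walk <- findPath(adj2, L)
        if (!is.null(walk)) { adj <- adj2; aa <- g2@aa; break }
      }
    }
    if (is.null(walk))
      stop("could not draw a simple walk of length ", L,
           " in the epitope graph")
    pep <- aa[walk]
    if (noise > 0) {
      pos <- sample(L, noise)
      pep[pos] <- sample(.AA_LETTERS, noise, replace = TRUE)
    }
    peps[k] <- paste(pep, collapse = "")
  }
  Biostrings::AAStringSet(peps)
}

#' Generate a labelled feature table with class imbalance
#'
#' Rows are drawn from two independent-normal populations over the eight
#' standard feature columns; positives are shifted by \code{shift} standard
#' deviations on \code{nShift} columns. Negatives outnumber positives by
#' \code{ratio} (about 8:1 in the real training data).
#'
#' @param nPositives positive (epitope) rows.
#' @param ratio negatives per positive.
#' @param shift mean shift of positives, in SD units.
#' @param nShift number of shifted feature columns.
#' @param seed integer seed.
#' @return data.frame of 8 feature columns plus binary \code{label}.
#' @export
syntheticLabelledTable <- function(nPositives = 20, ratio = 8, shift = 3,
                                   nShift = 2, seed = 1) {
  set.seed(seed)
  featNames <- c("propensity", "conservation", "sidechain_energy",
                 "contact_number", "planarity", "ss_helix", "ss_strand",
                 "ss_coil")
  nNeg <- nPositives * ratio
  n <- nPositives + nNeg
  x <- matrix(rnorm(n * base::length(featNames)), n,
              dimnames = list(NULL, featNames))
  x[seq_len(nPositives), seq_len(nShift)] <-
    x[seq_len(nPositives), seq_len(nShift)] + shift
  out <- data.frame(x, label = rep(c(1, 0), c(nPositives, nNeg)))
  rownames(out) <- paste0("r", seq_len(n))
  out
}
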