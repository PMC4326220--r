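#' AntigenStructure: a parsed antigen (optionally with binding partners)
#'
#' Holds the atom records of one antigen chain plus any partner (antibody or
#' ligand) chains, together with a per-residue table for the antigen chain.
#' Hetero records and waters are excluded at parse time; author residue
#' numbering and insertion codes are preserved verbatim.
#'
#' @slot pdbId 4-character PDB identifier or a synthetic tag.
#' @slot antigenChain single chain identifier of the antigen.
#' @slot partnerChains zero or more partner chain identifiers.
#' @slot atoms data.frame of atom records (chain, resno, insert, resid, elety,
#'   element, x, y, z, sidechain) covering antigen and partner chains.
#' @slot residues data.frame with one row per antigen residue (key, chain,
#'   resno, insert, aa, asa_total, asa_sidechain) in chain order.
#' @slot probeRadius solvent probe radius in Angstrom (default 1.4).
#' @export
setClass("AntigenStructure",
  representation(pdbId = "character", antigenChain = "character",
                 partnerChains = "character", atoms = "data.frame",
                 residues = "data.frame", probeRadius = "numeric"),
  prototype(partnerChains = character(0), probeRadius = 1.4))

setValidity("AntigenStructure", function(object) {
  msg <- character(0)
  if (nrow(object@residues) == 0L)
    msg <- c(msg, "empty antigen chain")
  if (object@probeRadius <= 0)
    msg <- c(msg, "probe radius must be positive")
  if (anyDuplicated(object@residues$key))
    msg <- c(msg, "duplicated residue identifiers in antigen chain")
  if (nrow(object@atoms) > 0 &&
      !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "non-finite atom coordinates")
  if (length(msg)) msg else TRUE
})

#' SurfaceSet: the solvent-exposed residues of an antigen
#'
#' The evaluation universe of the method: antigen residues whose side-chain
#' relative accessibility exceeds the surface threshold, in chain order,
#' possibly extended by annotated epitope residues that fail the filter
#' (flagged, so sensitivity bookkeeping never silently loses true positives).
#'
#' @slot structure the parent \linkS4class{AntigenStructure}.
#' @slot table per-residue data.frame (key, chain, resno, insert, aa,
#'   asa_total, asa_sidechain, rsa_sidechain, is_surface, is_epitope,
#'   ca_x, ca_y, ca_z).
#' @slot residues keys of the surface residues (the evaluation universe).
#' @slot rsaThreshold side-chain RSA cutoff (fraction, default 0.05).
#' @slot epitope keys of annotated epitope residues (may be empty).
#' @slot flags character vector of provenance/warning flags.
#' @export
setClass("SurfaceSet",
  representation(structure = "AntigenStructure", table = "data.frame",
                 residues = "character", rsaThreshold = "numeric",
                 epitope = "character", flags = "character"),
  prototype(rsaThreshold = 0.05, epitope = character(0),
            flags = character(0)))

setValidity("SurfaceSet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@residues))
    msg <- c(msg, "surface residues must be unique")
  if (!all(object@epitope %in% object@residues))
    msg <- c(msg, "annotated epitope must lie inside the evaluation universe")
  if (length(msg)) msg else TRUE
})

#' PatchGraph: the residue-adjacency graph of one surface patch
#'
#' Vertices are the patch's residues; edges join residue pairs whose C-alpha
#' distance is at most the patch's adaptive distance threshold (ADT), the
#' smallest stepped threshold giving a connected graph whose edge density
#' (compactness factor, CF) reaches the target.
#'
#' @slot center key of the seeding residue.
#' @slot members keys of the patch residues (center included).
#' @slot aa one-letter amino acids of the members (parallel to members).
#' @slot coords numeric matrix of member C-alpha coordinates.
#' @slot edges two-column integer matrix of member indices (u < v).
#' @slot adt the adaptive distance threshold chosen, Angstrom.
#' @slot cf the compactness (edge density) achieved.
#' @slot flags character flags ("cf unmet", "disconnected", ...).
#' @export
setClass("PatchGraph",
  representation(center = "character", members = "character",
                 aa = "character", coords = "matrix", edges = "matrix",
                 adt = "numeric", cf = "numeric", flags = "character"),
  prototype(flags = character(0)))

setValidity("PatchGraph", function(object) {
  msg <- character(0)
  if (!(object@center %in% object@members))
    msg <- c(msg, "center must be a member")
  if (nrow(object@edges) > 0) {
    if (any(object@edges[, 1] == object@edges[, 2]))
      msg <- c(msg, "self loops are not allowed")
    if (max(object@edges) > length(object@members) || min(object@edges) < 1)
      msg <- c(msg, "edge endpoints must index members")
  }
  if (length(object@aa) != length(object@members))
    msg <- c(msg, "aa must be parallel to members")
  if (length(msg)) msg else TRUE
})

#' EpitopeEnsemble: random forests trained on class-balanced subsamples
#'
#' Each member forest is trained on all epitope (positive) rows plus an
#' equally sized without-replacement draw of nonepitope rows; a surface
#' residue is kept when at least half of the members vote "epitope"
#' (ties resolve toward keeping, since pruning losses are irreversible
#' downstream).
#'
#' @slot members list of fitted randomForest objects.
#' @slot nMembers number of balanced subsets / forests.
#' @slot treesPerForest trees per member forest.
#' @slot featuresPerSplit variables tried at each split.
#' @slot seed integer seed that fully determines training.
#' @slot featureNames training feature column names, in order.
#' @export
setClass("EpitopeEnsemble",
  representation(members = "list", nMembers = "integer",
                 treesPerForest = "integer", featuresPerSplit = "integer",
                 seed = "integer", featureNames = "character"))

setValidity("EpitopeEnsemble", function(object) {
  msg <- character(0)
  if (object@nMembers < 1L) msg <- c(msg, "need at least one member forest")
  if (length(object@members) != object@nMembers)
    msg <- c(msg, "members length must equal nMembers")
  if (length(msg)) msg else TRUE
})

#' PrunedSurface: the ensemble's partition of the surface
#'
#' @slot kept keys predicted "epitope" (retained for patch search).
#' @slot removed keys predicted "nonepitope" (pruned).
#' @slot votes named integer vector of positive votes per residue.
#' @slot nMembers ensemble size the votes are out of.
#' @export
setClass("PrunedSurface",
  representation(kept = "character", removed = "character",
                 votes = "integer", nMembers = "integer"))

setValidity("PrunedSurface", function(object) {
  if (length(intersect(object@kept, object@removed)) > 0)
    "kept and removed must be disjoint" else TRUE
})

#' EpitopePrediction: the winning patch and its residues
#'
#' @slot predicted keys of the predicted epitope residues (empty when the
#'   method makes no prediction).
#' @slot winningCenter center key of the highest-scoring patch ("" if none).
#' @slot score the winning patch score (sum over mimotopes of -ln P).
#' @slot mode "patch" (all winning-patch residues) or "paths" (union of
#'   best-alignment paths).
#' @slot ranking data.frame of all patch scores, ranked.
#' @slot alignments list of best alignments for the winning patch.
#' @export
setClass("EpitopePrediction",
  representation(predicted = "character", winningCenter = "character",
                 score = "numeric", mode = "character", ranking = "data.frame",
                 alignments = "list"),
  prototype(predicted = character(0), winningCenter = "",
            score = NA_real_, mode = "patch", alignments = list()))

setMethod("show", "AntigenStructure", function(object) {
  cat("AntigenStructure", object@pdbId, "\n",
      " antigen chain ", object@antigenChain, ": ",
      nrow(object@residues), " residues, ",
      sum(object@atoms$chain == object@antigenChain), " atoms\n", sep = "")
  if (length(object@partnerChains))
    cat("  partner chains:", paste(object@partnerChains, collapse = ", "), "\n")
  if (!all(is.na(object@residues$asa_total)))
    cat("  ASA computed (probe ", object@probeRadius, " A)\n", sep = "")
})

setMethod("show", "SurfaceSet", function(object) {
  cat("SurfaceSet: ", length(object@residues), " surface residues ",
      "(side-chain RSA > ", object@rsaThreshold, ")\n", sep = "")
  if (length(object@epitope))
    cat("  annotated epitope:", length(object@epitope), "residues\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "PatchGraph", function(object) {
  cat("PatchGraph centered at ", object@center, ": ",
      length(object@members), " residues, ", nrow(object@edges),
      " edges (ADT ", object@adt, " A, CF ", round(object@cf, 3), ")\n",
      sep = "")
})

setMethod("show", "EpitopeEnsemble", function(object) {
  cat("EpitopeEnsemble: ", object@nMembers, " balanced forests x ",
      object@treesPerForest, " trees, ", object@featuresPerSplit,
      " features/split, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "PrunedSurface", function(object) {
  cat("PrunedSurface: ", length(object@kept), " kept, ",
      length(object@removed), " removed (votes out of ",
      object@nMembers, ")\n", sep = "")
})

setMethod("show", "EpitopePrediction", function(object) {
  if (length(object@predicted) == 0) {
    cat("EpitopePrediction: no prediction\n")
  } else {
    cat("EpitopePrediction (mode ", object@mode, "): ",
        length(object@predicted), " residues, winning patch ",
        object@winningCenter, " (score ", round(object@score, 3), ")\n",
        sep = "")
  }
})
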