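# Per-residue epitope propensity features. Each provider returns a numeric
# vector (or matrix) over the surface residues of a SurfaceSet; features that
# depend on a neighbourhood use C-alpha distances with a common smoothing
# radius (default 10 A, the typical spatial scale of an epitope patch).

.surfCoords <- function(surface) {
  tab <- surface@table
  tab <- tab[match(surface@residues, tab$key), , drop = FALSE]
  m <- as.matrix(tab[, c("ca_x", "ca_y", "ca_z")])
  rownames(m) <- tab$key
  m
}

.surfAA <- function(surface) {
  tab <- surface@table
  setNames(tab$aa[match(surface@residues, tab$key)], surface@residues)
}

.neighbourLists <- function(coords, radius) {
  d <- as.matrix(stats::dist(coords))
  lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= radius))
}

.readScale <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  setNames(tab$value, tab$aa)
}

#' Default feature scales
#'
#' The shipped defaults: a hydrophilicity-based residue epitope propensity
#' scale and a hydropathy-based side-chain energy scale, both editable
#' two-column TSVs (aa, value).
#' @return named numeric vector over the 20 amino acids.
#' @export
defaultPropensityScale <- function() {
  .readScale(system.file("extdata", "propensity_scale.tsv",
                         package = "mimoprune"))
}

#' @rdname defaultPropensityScale
#' @export
defaultSidechainEnergyScale <- function() {
  .readScale(system.file("extdata", "sidechain_energy_scale.tsv",
                         package = "mimoprune"))
}

# Neighbour-smoothed per-amino-acid scale lookup shared by the propensity
# and side-chain-energy providers.
.smoothedScale <- function(surface, scale, radius) {
  aa <- .surfAA(surface)
  raw <- unname(scale[aa])
  unknown <- is.na(raw)
  if (any(unknown)) {
    warning("unknown amino acids scored 0: ",
            paste(unique(aa[unknown]), collapse = ", "))
    raw[unknown] <- 0
  }
  nb <- .neighbourLists(.surfCoords(surface), radius)
  out <- vapply(nb, function(idx) mean(raw[idx]), numeric(1))
  setNames(out, surface@residues)
}

#' Residue epitope propensity
#'
#' Per-amino-acid propensity value, averaged over the residue's spatial
#' neighbours (C-alpha within \code{radius}, self included).
#'
#' @param surface a \linkS4class{SurfaceSet}.
#' @param scale named numeric per-amino-acid scale.
#' @param radius smoothing radius, A.
#' @return named numeric vector over surface residues.
#' @export
residuePropensity <- function(surface, scale = defaultPropensityScale(),
                              radius = 10) {
  .smoothedScale(surface, scale, radius)
}

#' Side-chain energy score
#'
#' Per-amino-acid side-chain energy value, neighbour-smoothed as for
#' \code{\link{residuePropensity}}.
#' @inheritParams residuePropensity
#' @return named numeric vector over surface residues.
#' @export
sidechainEnergy <- function(surface, scale = defaultSidechainEnergyScale(),
                            radius = 10) {
  .smoothedScale(surface, scale, radius)
}

#' Derive a log-odds propensity scale from a labelled residue table
#'
#' log((epitope frequency of aa) / (surface frequency of aa)), with add-one
#' smoothing; usable as the \code{scale} of \code{\link{residuePropensity}}.
#'
#' @param aa one-letter amino acids of the residues.
#' @param label binary epitope labels (1 = epitope).
#' @return named numeric vector over the 20 amino acids.
#' @export
propensityFromTable <- function(aa, label) {
  aa <- factor(aa, levels = .AA_LETTERS)
  pos <- table(aa[label == 1]) + 1
  all <- table(aa) + 1
  setNames(as.numeric(log((pos / sum(pos)) / (all / sum(all)))),
           .AA_LETTERS)
}

#' Evolutionary conservation score
#'
#' Shannon-entropy-based conservation per alignment column, rescaled to
#' [0, 1] (1 = fully conserved). Without an alignment every residue scores
#' the neutral fallback 0.5 and the result carries the flag
#' \code{"conservation:fallback"}.
#'
#' @param surface a \linkS4class{SurfaceSet}.
#' @param alignment optional character matrix, one row per homologous
#'   sequence, columns mapping 1:1 to the surface residues.
#' @return named numeric vector over surface residues (attribute
#'   \code{flags} records the fallback).
#' @export
conservationScore <- function(surface, alignment = NULL) {
  keys <- surface@residues
  if (is.null(alignment)) {
    out <- setNames(rep(0.5, length(keys)), keys)
    attr(out, "flags") <- "conservation:fallback"
    return(out)
  }
  alignment <- as.matrix(alignment)
  if (ncol(alignment) != length(keys))
    stop("alignment has ", ncol(alignment), " columns but the surface has ",
         length(keys), " residues")
  hmax <- log(20)
  cons <- apply(alignment, 2, function(col) {
    col <- toupper(col[col %in% .AA_LETTERS])
    if (length(col) == 0) return(0.5)
    p <- table(col) / length(col)
    1 - (-sum(p * log(p))) / hmax
  })
  setNames(as.numeric(cons), keys)
}

#' Contact number
#'
#' Count of other antigen surface residues whose C-alpha lies strictly
#' within \code{radius} of this residue's C-alpha (a residue never counts
#' itself).
#'
#' @inheritParams residuePropensity
#' @return named integer vector.
#' @export
contactNumber <- function(surface, radius = 10) {
  coords <- .surfCoords(surface)
  d <- as.matrix(stats::dist(coords))
  out <- vapply(seq_len(nrow(d)),
                function(i) sum(d[i, ] < radius & d[i, ] > 0), numeric(1))
  setNames(as.integer(out), surface@residues)
}

#' Surface planarity score
#'
#' RMSD (A) of the neighbourhood C-alpha coordinates from their
#' least-squares plane; neighbourhoods smaller than three residues score 0
#' and are flagged degenerate.
#'
#' @inheritParams residuePropensity
#' @return named numeric vector with a \code{flags} attribute.
#' @export
planarityScore <- function(surface, radius = 10) {
  coords <- .surfCoords(surface)
  nb <- .neighbourLists(coords, radius)
  flags <- character(0)
  out <- vapply(seq_along(nb), function(i) {
    idx <- nb[[i]]
    if (length(idx) < 3) {
      flags <<- c(flags, paste0("planarity_degenerate:",
                                surface@residues[i]))
      return(0)
    }
    planeRMSD(coords[idx, , drop = FALSE])
  }, numeric(1))
  out <- setNames(out, surface@residues)
  attr(out, "flags") <- flags
  out
}

# Backbone-dihedral secondary structure classes for all antigen residues.
# Returns named character H/E/C; residues with missing backbone are coil,
# flagged.
.assignSS <- function(structure) {
  res <- structure@residues
  at <- structure@atoms[structure@atoms$chain == structure@antigenChain, ,
                        drop = FALSE]
  akey <- residueKey(at$chain, at$resno, at$insert)
  getAtom <- function(key, name) {
    row <- at[akey == key & at$elety == name, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  n <- nrow(res)
  cls <- rep("C", n)
  flags <- character(0)
  for (i in seq_len(n)) {
    Ni <- getAtom(res$key[i], "N"); CAi <- getAtom(res$key[i], "CA")
    Ci <- getAtom(res$key[i], "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) {
      flags <- c(flags, paste0("ss_missing_backbone:", res$key[i]))
      next
    }
    phi <- if (i > 1) {
      Cp <- getAtom(res$key[i - 1], "C")
      if (is.null(Cp)) NA else dihedralAngle(Cp, Ni, CAi, Ci)
    } else NA
    psi <- if (i < n) {
      Nn <- getAtom(res$key[i + 1], "N")
      if (is.null(Nn)) NA else dihedralAngle(Ni, CAi, Ci, Nn)
    } else NA
    if (!is.na(phi) && !is.na(psi)) {
      if (phi >= -120 && phi <= -30 && psi >= -80 && psi <= -5) {
        cls[i] <- "H"
      } else if (phi >= -180 && phi <= -90 && (psi >= 90 || psi <= -150)) {
        cls[i] <- "E"
      }
    } else if (!is.na(phi) || !is.na(psi)) {
      # chain terminus: classify on the single defined dihedral
      a <- if (is.na(phi)) psi else phi
      if (is.na(phi) && a >= -80 && a <= -5) cls[i] <- "H"
      if (is.na(phi) && (a >= 90 || a <= -150)) cls[i] <- "E"
      if (is.na(psi) && a >= -120 && a <= -30) cls[i] <- "H"
      if (is.na(psi) && a < -120) cls[i] <- "E"
    }
  }
  out <- setNames(cls, res$key)
  attr(out, "flags") <- flags
  out
}

#' Secondary structure composition
#'
#' Each residue is assigned helix/strand/coil from its backbone dihedrals
#' (or from a supplied per-residue assignment), then the composition is the
#' fraction of each class among surface residues within \code{radius}.
#'
#' @inheritParams residuePropensity
#' @param assignment optional named character vector (H/E/C by residue key),
#'   e.g. mirrored from a DSSP-style run.
#' @return numeric matrix (rows = surface residues) with columns
#'   \code{ss_helix}, \code{ss_strand}, \code{ss_coil}; rows sum to 1.
#' @export
secondaryStructureComposition <- function(surface, radius = 10,
                                          assignment = NULL) {
  keys <- surface@residues
  if (is.null(assignment)) assignment <- .assignSS(surface@structure)
  cls <- assignment[keys]
  cls[is.na(cls)] <- "C"
  nb <- .neighbourLists(.surfCoords(surface), radius)
  out <- t(vapply(nb, function(idx) {
    k <- cls[idx]
    c(mean(k == "H"), mean(k == "E"), mean(k == "C"))
  }, numeric(3)))
  dimnames(out) <- list(keys, c("ss_helix", "ss_strand", "ss_coil"))
  out
}

#' Build the per-residue feature table
#'
#' One row per surface residue with the six epitope propensity features (the
#' secondary-structure composition expands to three columns, for eight
#' scalar columns total), in a fixed recorded order.
#'
#' @param surface a \linkS4class{SurfaceSet}.
#' @param radius neighbourhood radius shared by the spatial features, A.
#' @param propensityScale,energyScale per-amino-acid scales.
#' @param alignment optional conservation alignment
#'   (see \code{\link{conservationScore}}).
#' @param ssAssignment optional secondary-structure assignment.
#' @return data.frame keyed by residue (rownames), with attribute
#'   \code{feature_names} and accumulated \code{flags}.
#' @export
buildFeatureTable <- function(surface, radius = 10,
                              propensityScale = defaultPropensityScale(),
                              energyScale = defaultSidechainEnergyScale(),
                              alignment = NULL, ssAssignment = NULL) {
  cons <- conservationScore(surface, alignment)
  plan <- planarityScore(surface, radius)
  ss <- secondaryStructureComposition(surface, radius, ssAssignment)
  tab <- data.frame(
    propensity = residuePropensity(surface, propensityScale, radius),
    conservation = as.numeric(cons),
    sidechain_energy = sidechainEnergy(surface, energyScale, radius),
    contact_number = as.numeric(contactNumber(surface, radius)),
    planarity = as.numeric(plan),
    ss_helix = ss[, 1], ss_strand = ss[, 2], ss_coil = ss[, 3],
    row.names = surface@residues)
  stopifnot(!anyNA(tab))
  attr(tab, "feature_names") <- colnames(tab)
  attr(tab, "flags") <- c(attr(cons, "flags"), attr(plan, "flags"))
  tab
}

#' Read/write feature tables as TSV
#'
#' The TSV carries a \code{#columns} header line recording the feature
#' order; the first column is the residue key.
#' @param table a feature table (from \code{\link{buildFeatureTable}}).
#' @param path file path.
#' @return \code{readFeatureTable}: the table; \code{writeFeatureTable}:
#'   the path, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#columns: ", paste(colnames(table), collapse = "\t")),
             con)
  write.table(data.frame(key = rownames(table), table,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  out <- tab[, -1, drop = FALSE]
  rownames(out) <- tab$key
  attr(out, "feature_names") <- colnames(out)
  out
}
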