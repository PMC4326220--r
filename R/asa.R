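# van der Waals radii (Angstrom) for heavy atoms; unknown elements fall
# back to carbon.
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

.vdwRadius <- function(element) {
  r <- .VDW[element]
  r[is.na(r)] <- .VDW[["C"]]
  unname(r)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Shrake-Rupley rolling-probe ASA for a set of heavy atoms.
# Returns the accessible area (A^2) of each atom's probe-expanded sphere.
.atomASA <- function(xyz, radii, probe = 1.4, nPoints = 960) {
  n <- nrow(xyz)
  if (n == 0L) return(numeric(0))
  pts <- .spherePoints(nPoints)
  R <- radii + probe
  asa <- numeric(n)
  eps2 <- 1e-12
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    # exactly coincident spheres count their shared surface once: every
    # atom but the first of a coincident group is fully buried
    co <- which(d2 < eps2 & R >= R[i])
    if (any(co < i) || any(co[R[co] > R[i]] != i)) {
      asa[i] <- 0
      next
    }
    nb <- setdiff(which(d2 < (R[i] + R)^2 & d2 > eps2), i)
    if (length(nb) == 0L) {
      asa[i] <- 4 * pi * R[i]^2
      next
    }
    sp <- pts * R[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
            (sp[free, 3] - xyz[j, 3])^2
      free[free] <- dj > R[j]^2
    }
    asa[i] <- 4 * pi * R[i]^2 * sum(free) / nPoints
  }
  asa
}

#' Compute per-residue accessible surface area
#'
#' Rolling-probe (Shrake-Rupley) ASA with a fixed, configurable sphere-point
#' count, computed in the context of the selected chains. Antigen residues
#' get their total and side-chain ASA filled in; burying context atoms from
#' partner chains lower the values but are not themselves summed.
#'
#' @param structure an \linkS4class{AntigenStructure}.
#' @param chains chain identifiers forming the occlusion context; default the
#'   antigen chain alone.
#' @param nPoints sphere sample points per atom (default 960; deterministic).
#' @return the structure with \code{asa_total}/\code{asa_sidechain} filled.
#' @export
computeASA <- function(structure, chains = structure@antigenChain,
                       nPoints = 960) {
  at <- structure@atoms[structure@atoms$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms in selected chains")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  asa <- .atomASA(xyz, .vdwRadius(at$element),
                  probe = structure@probeRadius, nPoints = nPoints)
  res <- structure@residues
  akey <- residueKey(at$chain, at$resno, at$insert)
  tot <- tapply(asa, factor(akey, levels = res$key), sum)
  sc <- tapply(asa * at$sidechain, factor(akey, levels = res$key), sum)
  res$asa_total <- as.numeric(ifelse(is.na(tot), 0, tot))
  res$asa_sidechain <- as.numeric(ifelse(is.na(sc), 0, sc))
  missing <- !(res$key %in% akey)
  if (any(missing))
    warning("residues with no atoms assigned ASA 0: ",
            paste(res$key[missing], collapse = ", "))
  structure@residues <- res
  structure
}

#' Reference maximal accessible surface areas
#'
#' Per-amino-acid maxima used to normalise ASA into relative accessibility.
#' The shipped table holds theoretical Gly-X-Gly tripeptide maxima for the
#' whole residue; the side-chain reference is the whole-residue maximum minus
#' the glycine value, with glycine itself (no side chain) keeping its
#' whole-residue reference. Any two-column TSV (aa, then total and/or
#' sidechain) can be supplied instead.
#'
#' @param file optional TSV with columns \code{aa}, \code{total},
#'   \code{sidechain}; default the shipped scale.
#' @return data.frame with columns aa, total, sidechain.
#' @export
maxAsaReference <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "max_asa_reference.tsv",
                        package = "mimoprune")
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#")
}

# C-alpha coordinates per antigen residue (side-chain centroid fallback,
# flagged via attribute).
.caCoords <- function(structure) {
  at <- structure@atoms[structure@atoms$chain == structure@antigenChain, ,
                        drop = FALSE]
  res <- structure@residues
  akey <- residueKey(at$chain, at$resno, at$insert)
  out <- matrix(NA_real_, nrow(res), 3,
                dimnames = list(res$key, c("x", "y", "z")))
  flagged <- character(0)
  for (i in seq_len(nrow(res))) {
    rows <- at[akey == res$key[i], , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca) >= 1) {
      out[i, ] <- as.numeric(ca[1, c("x", "y", "z")])
    } else {
      sc <- rows[rows$sidechain, , drop = FALSE]
      if (nrow(sc) == 0) sc <- rows
      out[i, ] <- colMeans(as.matrix(sc[, c("x", "y", "z")]))
      flagged <- c(flagged, res$key[i])
    }
  }
  attr(out, "centroid_fallback") <- flagged
  out
}

#' Extract the antigen surface residue set
#'
#' A residue belongs to the surface when the relative accessibility of its
#' side chain, computed on the antigen chain alone (partners excluded from
#' the occlusion context), exceeds \code{rsaThreshold}. Residues of unknown
#' type with no reference value are excluded with a warning.
#'
#' @param structure an \linkS4class{AntigenStructure}.
#' @param rsaThreshold side-chain RSA cutoff, fraction (default 0.05).
#' @param reference reference maxima, see \code{\link{maxAsaReference}}.
#' @param nPoints sphere sample points for the ASA computation.
#' @return a \linkS4class{SurfaceSet} (epitope slot empty).
#' @export
extractSurface <- function(structure, rsaThreshold = 0.05,
                           reference = maxAsaReference(), nPoints = 960) {
  structure <- computeASA(structure, chains = structure@antigenChain,
                          nPoints = nPoints)
  res <- structure@residues
  flags <- character(0)
  ref_tot <- setNames(reference$total, reference$aa)
  ref_sc <- setNames(reference$sidechain, reference$aa)
  known <- res$aa %in% reference$aa
  if (any(!known)) {
    warning("excluding residues with no reference ASA: ",
            paste(res$key[!known], collapse = ", "))
    flags <- c(flags, paste0("no_reference:", res$key[!known]))
  }
  # glycine has no side chain: its whole-residue ASA is judged against the
  # whole-residue reference
  num <- ifelse(res$aa == "G", res$asa_total, res$asa_sidechain)
  den <- ifelse(res$aa == "G", ref_tot[res$aa], ref_sc[res$aa])
  rsa <- ifelse(known, num / den, NA_real_)
  ca <- .caCoords(structure)
  if (length(attr(ca, "centroid_fallback")))
    flags <- c(flags, paste0("ca_centroid_fallback:",
                             attr(ca, "centroid_fallback")))
  tab <- data.frame(res, rsa_sidechain = as.numeric(rsa),
                    is_surface = known & !is.na(rsa) & rsa > rsaThreshold,
                    is_epitope = FALSE,
                    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  new("SurfaceSet", structure = structure, table = tab,
      residues = tab$key[tab$is_surface], rsaThreshold = rsaThreshold,
      epitope = character(0), flags = flags)
}

#' Annotate true epitope residues from an antigen-antibody complex
#'
#' Default definition: a residue is epitopic when its total ASA decreases by
#' more than \code{deltaAsaThreshold} once the partner chains enter the
#' occlusion context. A contact-distance alternative (any heavy-atom pair
#' within \code{contactDistance} of a partner atom) is available via
#' \code{mode = "contact"}. Annotated epitope residues that fail the surface
#' filter are still added to the evaluation universe, flagged, so sensitivity
#' denominators never lose true positives.
#'
#' @param structure an \linkS4class{AntigenStructure} with partner chains.
#' @param deltaAsaThreshold ASA-loss cutoff in A^2 (default 1.0).
#' @param rsaThreshold surface cutoff passed to \code{\link{extractSurface}}.
#' @param mode "dasa" (default) or "contact".
#' @param contactDistance heavy-atom cutoff for \code{mode="contact"}, A.
#' @param reference,nPoints passed to \code{\link{extractSurface}}.
#' @return a \linkS4class{SurfaceSet} with the epitope slot filled.
#' @export
annotateEpitope <- function(structure, deltaAsaThreshold = 1.0,
                            rsaThreshold = 0.05,
                            mode = c("dasa", "contact"),
                            contactDistance = 4.0,
                            reference = maxAsaReference(), nPoints = 960) {
  mode <- match.arg(mode)
  if (length(structure@partnerChains) == 0L)
    stop("cannot annotate epitope without binding partner")
  surf <- extractSurface(structure, rsaThreshold = rsaThreshold,
                         reference = reference, nPoints = nPoints)
  tab <- surf@table
  if (mode == "dasa") {
    alone <- tab$asa_total
    complexed <- computeASA(structure,
                            chains = c(structure@antigenChain,
                                       structure@partnerChains),
                            nPoints = nPoints)@residues$asa_total
    epi <- tab$key[(alone - complexed) > deltaAsaThreshold]
  } else {
    at <- structure@atoms
    ag <- at[at$chain == structure@antigenChain, , drop = FALSE]
    pa <- at[at$chain %in% structure@partnerChains, , drop = FALSE]
    if (nrow(pa) == 0L)
      stop("cannot annotate epitope without binding partner")
    axyz <- as.matrix(ag[, c("x", "y", "z")])
    pxyz <- as.matrix(pa[, c("x", "y", "z")])
    mind <- vapply(seq_len(nrow(axyz)), function(i) {
      min(sqrt((pxyz[, 1] - axyz[i, 1])^2 + (pxyz[, 2] - axyz[i, 2])^2 +
               (pxyz[, 3] - axyz[i, 3])^2))
    }, numeric(1))
    akey <- residueKey(ag$chain, ag$resno, ag$insert)
    epi <- unique(akey[mind <= contactDistance])
    epi <- tab$key[tab$key %in% epi]
  }
  universe <- tab$key[tab$is_surface]
  sunken <- setdiff(epi, universe)
  flags <- surf@flags
  if (length(sunken)) {
    universe <- tab$key[tab$is_surface | tab$key %in% sunken]
    flags <- c(flags, paste0("epitope_below_surface_threshold:", sunken))
  }
  tab$is_epitope <- tab$key %in% epi
  new("SurfaceSet", structure = surf@structure, table = tab,
      residues = universe, rsaThreshold = rsaThreshold,
      epitope = epi, flags = flags)
}
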