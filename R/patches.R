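# Overlapping surface patches and their residue-adjacency graphs. A patch is
# seeded at every surface residue; its graph uses the smallest stepped
# C-alpha distance threshold (ADT) that yields a connected graph whose edge
# density (compactness factor, CF) reaches the target, so sparse regions get
# larger thresholds and compact regions stay free of spurious edges.

#' Divide the surface into overlapping patches
#'
#' One patch per surface residue (the center); members are the surface
#' residues whose C-alpha lies within \code{radius} of the center's.
#'
#' @param surface a \linkS4class{SurfaceSet} (possibly pruned).
#' @param radius patch radius, A (default 12).
#' @return list of patches, each \code{list(center, members)}; empty list
#'   for an empty surface (callers must then report "no prediction").
#' @export
makePatches <- function(surface, radius = 12) {
  keys <- surface@residues
  if (length(keys) == 0L) return(list())
  coords <- .surfCoords(surface)
  d <- as.matrix(stats::dist(coords))
  lapply(seq_along(keys), function(i) {
    list(center = keys[i], members = keys[d[i, ] <= radius])
  })
}

# Stepped search for the adaptive distance threshold of one patch.
# coords: member C-alpha matrix. Returns list(adt, edges, cf, flags).
.adaptiveThreshold <- function(coords, cfTarget, adtMin = 4, adtMax = 9,
                               step = 0.5) {
  m <- nrow(coords)
  if (m < 2)
    return(list(adt = adtMin, edges = matrix(integer(0), 0, 2), cf = 1,
                flags = "singleton"))
  d <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  npairs <- nrow(pairs)
  thresholds <- seq(adtMin, adtMax, by = step)
  best_connected <- NULL
  for (adt in thresholds) {
    sel <- d[pairs] <= adt
    edges <- pairs[sel, , drop = FALSE]
    g <- igraph::make_empty_graph(n = m, directed = FALSE)
    if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
    connected <- nrow(edges) >= m - 1 && igraph::is_connected(g)
    cf <- nrow(edges) / npairs
    if (connected) {
      best_connected <- list(adt = adt, edges = edges, cf = cf)
      if (cf >= cfTarget)
        return(list(adt = adt, edges = edges, cf = cf,
                    flags = character(0)))
    }
  }
  if (!is.null(best_connected)) {
    # no threshold met the CF target: keep the largest-ADT connected graph
    sel <- d[pairs] <= adtMax
    edges <- pairs[sel, , drop = FALSE]
    return(list(adt = adtMax, edges = edges, cf = nrow(edges) / npairs,
                flags = "cf unmet"))
  }
  list(adt = adtMax,
       edges = pairs[d[pairs] <= adtMax, , drop = FALSE],
       cf = sum(d[pairs] <= adtMax) / npairs,
       flags = "disconnected")
}

#' Build the residue-adjacency graph of one patch
#'
#' Runs the adaptive-threshold search and wraps the result. If even the
#' largest threshold leaves the patch disconnected, only the connected
#' component containing the center is kept (flagged).
#'
#' @param patch a patch from \code{\link{makePatches}}.
#' @param surface the \linkS4class{SurfaceSet} the patch was cut from.
#' @param cfTarget compactness (edge density) target in (0, 1].
#' @param adtMin,adtMax,step threshold search grid, A.
#' @return a \linkS4class{PatchGraph}.
#' @export
buildPatchGraph <- function(patch, surface, cfTarget = 0.35,
                            adtMin = 4, adtMax = 9, step = 0.5) {
  keys <- patch$members
  coords <- .surfCoords(surface)[keys, , drop = FALSE]
  aa <- .surfAA(surface)[keys]
  res <- .adaptiveThreshold(coords, cfTarget, adtMin, adtMax, step)
  edges <- res$edges
  flags <- res$flags
  if ("disconnected" %in% flags && length(keys) > 1) {
    g <- igraph::make_empty_graph(n = length(keys), directed = FALSE)
    if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    keep <- which(comp == comp[match(patch$center, keys)])
    warning("patch at ", patch$center,
            " disconnected at maximum ADT; keeping center component (",
            length(keep), "/", length(keys), " residues)")
    sel <- edges[, 1] %in% keep & edges[, 2] %in% keep
    remap <- match(seq_along(keys), keep)
    edges <- cbind(remap[edges[sel, 1]], remap[edges[sel, 2]])
    keys <- keys[keep]
    coords <- coords[keep, , drop = FALSE]
    aa <- aa[keep]
    flags <- c(flags, "kept center component")
  }
  if (nrow(edges) == 0) edges <- matrix(integer(0), 0, 2)
  new("PatchGraph", center = patch$center, members = keys,
      aa = unname(aa), coords = coords,
      edges = matrix(as.integer(edges), ncol = 2),
      adt = res$adt, cf = res$cf, flags = flags)
}

#' Build patch graphs for a whole surface
#'
#' Convenience wrapper: \code{\link{makePatches}} then
#' \code{\link{buildPatchGraph}} per patch.
#'
#' @inheritParams buildPatchGraph
#' @inheritParams makePatches
#' @return list of \linkS4class{PatchGraph} objects.
#' @export
buildPatchGraphs <- function(surface, radius = 12, cfTarget = 0.35,
                             adtMin = 4, adtMax = 9, step = 0.5) {
  lapply(makePatches(surface, radius), buildPatchGraph, surface = surface,
         cfTarget = cfTarget, adtMin = adtMin, adtMax = adtMax, step = step)
}

#' Dump patch edges as a TSV edge list
#'
#' Debug output: one row per edge (center, u, v, dist).
#' @param graphs list of \linkS4class{PatchGraph}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePatchEdges <- function(graphs, path) {
  rows <- do.call(rbind, lapply(graphs, function(g) {
    if (nrow(g@edges) == 0) return(NULL)
    u <- g@edges[, 1]; v <- g@edges[, 2]
    d <- sqrt(rowSums((g@coords[u, , drop = FALSE] -
                       g@coords[v, , drop = FALSE])^2))
    data.frame(center = g@center, u = g@members[u], v = g@members[v],
               dist = round(d, 3))
  }))
  if (is.null(rows))
    rows <- data.frame(center = character(0), u = character(0),
                       v = character(0), dist = numeric(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
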