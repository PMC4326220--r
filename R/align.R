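# Mimotope-to-patch alignment and extreme-value scoring. The complete
# search itself lives in src/align.cpp; this file handles peptide and
# matrix I/O, the Gumbel calibration, and patch scoring/ranking.

.ALPHABET <- c(.AA_LETTERS, "X")

#' Read a mimotope set
#'
#' Accepts FASTA or one-peptide-per-line text. Peptides are uppercased and
#' validated against the 20 standard amino acids; duplicates are retained,
#' since biopanning multiplicity is signal.
#'
#' @param path input file.
#' @param minLength minimum peptide length (default 3).
#' @return a \link[Biostrings]{AAStringSet} of mimotopes.
#' @export
readMimotopes <- function(path, minLength = 3) {
  if (!file.exists(path)) stop("cannot read mimotope file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- trimws(lines)
  if (any(startsWith(nonempty, ">"))) {
    peps <- character(0)
    cur <- ""
    for (ln in nonempty) {
      if (startsWith(ln, ">")) {
        if (nzchar(cur)) peps <- c(peps, cur)
        cur <- ""
      } else cur <- paste0(cur, ln)
    }
    if (nzchar(cur)) peps <- c(peps, cur)
  } else {
    peps <- nonempty[nzchar(nonempty)]
  }
  if (length(peps) == 0L) stop("no mimotopes in ", path)
  peps <- toupper(peps)
  for (i in seq_along(peps)) {
    bad <- !strsplit(peps[i], "")[[1]] %in% .AA_LETTERS
    if (any(bad))
      stop("non-amino-acid character in mimotope ", i, ": ", peps[i])
    if (nchar(peps[i]) < minLength)
      stop("mimotope ", i, " shorter than ", minLength, ": ", peps[i])
  }
  Biostrings::AAStringSet(peps)
}

#' Substitution matrices
#'
#' \code{substitutionMatrix} returns a named scoring matrix: either one of
#' the BLOSUM matrices shipped with \pkg{Biostrings} (by name) or any file
#' in NCBI matrix text format. The package default is BLOSUM62.
#'
#' @param name matrix name ("BLOSUM62", "BLOSUM45", ...) or a file path.
#' @return numeric matrix with amino-acid dimnames.
#' @export
substitutionMatrix <- function(name = "BLOSUM62") {
  if (file.exists(name)) return(readSubstitutionMatrix(name))
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @rdname substitutionMatrix
#' @param path NCBI-format matrix file (comment lines \code{#}, a header row
#'   of residue letters, then one row per residue).
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  m <- matrix(NA_real_, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, "", 1), header))
  for (i in seq_along(rows))
    m[i, ] <- as.numeric(rows[[i]][-1])
  m
}

# Expand a user matrix onto the internal 21-letter alphabet (X scores the
# matrix's X entries when present, 0 otherwise).
.scoreMatrix <- function(matrix) {
  out <- matrix(0, length(.ALPHABET), length(.ALPHABET),
                dimnames = list(.ALPHABET, .ALPHABET))
  common <- intersect(.ALPHABET, rownames(matrix))
  out[common, intersect(.ALPHABET, colnames(matrix))] <-
    matrix[common, intersect(.ALPHABET, colnames(matrix))]
  out
}

.aaIndex <- function(aa) {
  idx <- match(aa, .ALPHABET)
  idx[is.na(idx)] <- match("X", .ALPHABET)
  idx
}

#' Align one peptide to the simple paths of a patch graph
#'
#' Finds the simple path maximising the summed substitution score of the
#' peptide against the path residues, allowing up to \code{maxSkips} peptide
#' positions to be skipped at \code{gapPenalty} each. The search is complete
#' (identical to exhaustive enumeration over simple paths); branch-and-bound
#' pruning only reduces node expansions. When the peptide cannot be placed
#' in full, the best shorter-coverage alignment is returned with
#' \code{complete = FALSE}.
#'
#' @param graph a \linkS4class{PatchGraph}.
#' @param peptide amino-acid string (length >= 3).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gapPenalty score for each skipped position (<= 0, default -4).
#' @param maxSkips maximum skipped positions (default 2).
#' @return list with \code{path} (residue keys), \code{score},
#'   \code{complete}, \code{matched}, \code{skips}, \code{expansions}.
#' @export
alignPeptideToGraph <- function(graph, peptide,
                                matrix = substitutionMatrix(),
                                gapPenalty = -4, maxSkips = 2) {
  peptide <- toupper(peptide)
  if (nchar(peptide) < 3) stop("peptide shorter than 3: ", peptide)
  sm <- .scoreMatrix(matrix)
  res <- .alignPeptideCpp(
    graph@edges, .aaIndex(graph@aa), length(graph@members),
    .aaIndex(strsplit(peptide, "")[[1]]), sm, gapPenalty, as.integer(maxSkips))
  res$path <- graph@members[res$path]
  res$peptide <- peptide
  res
}

#' Fit a Gumbel (Type-I extreme value) distribution by moments
#'
#' \code{beta = s * sqrt(6) / pi}, \code{mu = m - gamma * beta} with gamma
#' the Euler-Mascheroni constant; a zero-variance sample gets the floor
#' \code{beta = 1e-6} and the flag "degenerate null".
#'
#' @param scores numeric sample (e.g. best alignment scores of random
#'   peptides).
#' @return list with \code{mu}, \code{beta}, \code{n}, \code{flags}.
#' @export
gumbelFit <- function(scores) {
  scores <- scores[is.finite(scores)]
  m <- mean(scores)
  s <- stats::sd(scores)
  beta <- s * sqrt(6) / pi
  flags <- character(0)
  if (!is.finite(beta) || beta < 1e-6) {
    beta <- 1e-6
    flags <- "degenerate null"
  }
  list(mu = m - 0.5772156649015329 * beta, beta = beta,
       n = length(scores), flags = flags)
}

#' Calibrate the extreme-value null for one patch graph and peptide length
#'
#' Aligns \code{nSamples} random peptides (uniform amino-acid composition)
#' of the given length to the graph and fits a Gumbel distribution to the
#' best scores. Deterministic given \code{seed}.
#'
#' @inheritParams alignPeptideToGraph
#' @param length peptide length to calibrate for.
#' @param nSamples random peptides to draw (>= 100 recommended).
#' @param seed integer seed.
#' @return list (class \code{evdCalibration}) with \code{mu}, \code{beta},
#'   \code{n}, \code{seed}, \code{length}, \code{flags}.
#' @export
calibrateEVD <- function(graph, length, matrix = substitutionMatrix(),
                         gapPenalty = -4, maxSkips = 2, nSamples = 1000,
                         seed = 1) {
  sm <- .scoreMatrix(matrix)
  scores <- .calibrateScoresCpp(
    graph@edges, .aaIndex(graph@aa), base::length(graph@members),
    as.integer(length), sm, gapPenalty, as.integer(maxSkips),
    as.integer(nSamples), as.integer(seed), base::length(.AA_LETTERS))
  fit <- gumbelFit(scores)
  structure(list(mu = fit$mu, beta = fit$beta, n = as.integer(nSamples),
                 seed = as.integer(seed), length = as.integer(length),
                 flags = fit$flags),
            class = "evdCalibration")
}

#' Extreme-value P-value of a raw alignment score
#'
#' \code{p = 1 - exp(-exp(-(raw - mu)/beta))}, clamped to [1e-300, 1].
#'
#' @param rawScore raw alignment score(s).
#' @param cal a calibration from \code{\link{calibrateEVD}} or
#'   \code{\link{gumbelFit}}.
#' @return numeric P-value(s) in (0, 1].
#' @export
evdPValue <- function(rawScore, cal) {
  z <- (rawScore - cal$mu) / cal$beta
  p <- -expm1(-exp(-z))
  pmin(pmax(p, 1e-300), 1)
}

#' Score and rank all patches against a mimotope set
#'
#' For each patch graph, the extreme-value null is calibrated per distinct
#' peptide length (shared seed), every mimotope is aligned, and the patch
#' score is the Fisher-style sum of \code{-ln P} over best complete
#' alignments. Patches with no complete alignment for any mimotope are
#' dropped; if none remain the ranking is empty and the method makes no
#' prediction. Ties rank the larger patch first, then by residue-id order.
#'
#' @param graphs list of \linkS4class{PatchGraph} objects.
#' @param mimotopes an \link[Biostrings]{AAStringSet} or character vector.
#' @inheritParams calibrateEVD
#' @return object of class \code{patchScores}: list with \code{ranking}
#'   (data.frame center/score/n_members), \code{graphs} (by center) and
#'   \code{alignments} (by center).
#' @export
scorePatches <- function(graphs, mimotopes, matrix = substitutionMatrix(),
                         gapPenalty = -4, maxSkips = 2, nSamples = 1000,
                         seed = 1) {
  peps <- as.character(mimotopes)
  if (length(graphs) == 0L || length(peps) == 0L)
    return(structure(list(ranking = data.frame(center = character(0),
                                               score = numeric(0),
                                               n_members = integer(0)),
                          graphs = list(), alignments = list()),
                     class = "patchScores"))
  centers <- vapply(graphs, function(g) g@center, "")
  rows <- list()
  alnByCenter <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    cal <- list()
    for (len in unique(nchar(peps)))
      cal[[as.character(len)]] <- calibrateEVD(
        g, len, matrix = matrix, gapPenalty = gapPenalty,
        maxSkips = maxSkips, nSamples = nSamples, seed = seed)
    score <- 0
    any_complete <- FALSE
    alns <- vector("list", length(peps))
    for (pi in seq_along(peps)) {
      aln <- alignPeptideToGraph(g, peps[pi], matrix = matrix,
                                 gapPenalty = gapPenalty,
                                 maxSkips = maxSkips)
      if (isTRUE(aln$complete)) {
        aln$p_value <- evdPValue(aln$score,
                                 cal[[as.character(nchar(peps[pi]))]])
        score <- score + (-log(aln$p_value))
        any_complete <- TRUE
      } else {
        aln$p_value <- NA_real_
      }
      alns[[pi]] <- aln
    }
    if (any_complete) {
      rows[[length(rows) + 1L]] <-
        data.frame(center = g@center, score = score,
                   n_members = length(g@members))
      alnByCenter[[g@center]] <- alns
    }
  }
  if (length(rows) == 0L)
    return(structure(list(ranking = data.frame(center = character(0),
                                               score = numeric(0),
                                               n_members = integer(0)),
                          graphs = setNames(graphs, centers),
                          alignments = list()),
                     class = "patchScores"))
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$score, -ranking$n_members,
                           ranking$center), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, graphs = setNames(graphs, centers),
                 alignments = alnByCenter),
            class = "patchScores")
}

#' Emit the predicted epitope from a patch ranking
#'
#' Mode "patch" (default) predicts every residue of the highest-scoring
#' patch; mode "paths" predicts only the union of the best-alignment paths
#' on that patch. An empty ranking yields a "no prediction" result with an
#' empty residue set.
#'
#' @param scored a \code{patchScores} object from \code{\link{scorePatches}}.
#' @param mode "patch" or "paths".
#' @return an \linkS4class{EpitopePrediction}.
#' @export
predictEpitope <- function(scored, mode = c("patch", "paths")) {
  mode <- match.arg(mode)
  rk <- scored$ranking
  if (nrow(rk) == 0L)
    return(new("EpitopePrediction", predicted = character(0),
               winningCenter = "", score = NA_real_, mode = mode,
               ranking = rk, alignments = list()))
  win <- rk$center[1]
  g <- scored$graphs[[win]]
  alns <- scored$alignments[[win]]
  predicted <- if (mode == "patch") {
    g@members
  } else {
    unique(unlist(lapply(alns, function(a)
      if (isTRUE(a$complete)) a$path else NULL)))
  }
  new("EpitopePrediction", predicted = predicted, winningCenter = win,
      score = rk$score[1], mode = mode, ranking = rk, alignments = alns)
}
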