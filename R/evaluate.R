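# Residue-level performance measures over the antigen-surface universe:
# the total surface residue count is TP + FP + FN + TN, so specificity and
# accuracy are judged against every exposed residue, not only the
# neighbourhood of the prediction.

#' Confusion counts over the antigen surface
#'
#' \code{tp = |predicted & epitope|}, \code{fp = |predicted \\ epitope|},
#' \code{fn = |epitope \\ predicted|}, \code{tn} the remaining surface
#' residues. Predicted or epitope residues outside the surface universe are
#' clamped out with a warning.
#'
#' @param predicted predicted epitope residue identifiers.
#' @param epitope true epitope residue identifiers.
#' @param surface the surface residue universe (identifiers).
#' @return named integer vector (tp, fp, tn, fn), class
#'   \code{confusionCounts}.
#' @export
confusionCounts <- function(predicted, epitope, surface) {
  predicted <- unique(predicted)
  epitope <- unique(epitope)
  surface <- unique(surface)
  outP <- setdiff(predicted, surface)
  outE <- setdiff(epitope, surface)
  if (length(outP) || length(outE)) {
    warning("clamping ", length(outP), " predicted and ", length(outE),
            " epitope residues outside the surface universe")
    predicted <- intersect(predicted, surface)
    epitope <- intersect(epitope, surface)
  }
  tp <- length(intersect(predicted, epitope))
  fp <- length(setdiff(predicted, epitope))
  fn <- length(setdiff(epitope, predicted))
  tn <- length(surface) - tp - fp - fn
  out <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(sum(out) == length(surface))
  class(out) <- c("confusionCounts", class(out))
  out
}

# round half-up (display convention for reported tables; R's round() is
# half-even)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The six performance measures
#'
#' Sensitivity, specificity, precision (PPV), Matthews correlation
#' coefficient, accuracy and F-measure from confusion counts. Any metric
#' with a zero denominator is defined as 0 and flagged. Two MCC variants are
#' provided: \code{"standard"} (denominator
#' \code{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}) and \code{"paper"}, which replaces
#' the \code{(tp+fn)} factor by \code{(tp+tn)} — the form the published
#' benchmark table of this method was computed with; the two disagree in
#' general and both are exposed rather than silently reconciled.
#'
#' @param counts a \code{confusionCounts} vector (or anything with named
#'   elements tp, fp, tn, fn).
#' @param mccVariant "standard" (default) or "paper".
#' @return one-row data.frame (sen, spe, ppv, mcc, acc, f, mcc_variant) with
#'   a \code{flags} attribute.
#' @export
epitopeMetrics <- function(counts, mccVariant = c("standard", "paper")) {
  mccVariant <- match.arg(mccVariant)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, paste0("zero_denominator:", name))
      return(0)
    }
    num / den
  }
  sen <- safe(tp, tp + fn, "sen")
  spe <- safe(tn, fp + tn, "spe")
  ppv <- safe(tp, tp + fp, "ppv")
  acc <- safe(tp + tn, tp + fp + tn + fn, "acc")
  f <- if ((ppv + sen) == 0) {
    flags <- c(flags, "zero_denominator:f"); 0
  } else 2 * ppv * sen / (ppv + sen)
  mccDen2 <- if (mccVariant == "standard") tp + fn else tp + tn
  den <- sqrt(prod(c(tp + fp, mccDen2, tn + fp, tn + fn)))
  mcc <- if (den == 0) {
    flags <- c(flags, "zero_denominator:mcc"); 0
  } else (tp * tn - fp * fn) / den
  out <- data.frame(sen = sen, spe = spe, ppv = ppv, mcc = mcc,
                    acc = acc, f = f, mcc_variant = mccVariant)
  attr(out, "flags") <- flags
  out
}

#' Evaluate one prediction against an annotated surface
#'
#' @param prediction an \linkS4class{EpitopePrediction} (or a character
#'   vector of predicted residue identifiers).
#' @param surface a \linkS4class{SurfaceSet} carrying an annotated epitope.
#' @param mccVariant passed to \code{\link{epitopeMetrics}}.
#' @return list with \code{counts}, \code{metrics} (full precision) and
#'   \code{rounded} (2-decimal display values, half-up).
#' @export
evaluateCase <- function(prediction, surface,
                         mccVariant = c("standard", "paper")) {
  predicted <- if (is(prediction, "EpitopePrediction"))
    prediction@predicted else prediction
  if (length(surface@epitope) == 0L)
    stop("no ground truth: surface carries no annotated epitope")
  counts <- confusionCounts(predicted, surface@epitope, surface@residues)
  metrics <- epitopeMetrics(counts, mccVariant)
  rounded <- metrics
  num <- vapply(metrics, is.numeric, logical(1))
  rounded[num] <- lapply(metrics[num], roundHalfUp)
  list(counts = counts, metrics = metrics, rounded = rounded)
}

#' Column means of a metric table
#'
#' Unweighted arithmetic means per numeric column, reported both at full
#' precision and rounded half-up to 2 decimals (the display convention of
#' the benchmark tables).
#'
#' @param rows data.frame of per-case metric rows.
#' @return list with \code{mean} (full precision named vector) and
#'   \code{rounded}.
#' @export
summarizeMetrics <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  num <- vapply(rows, is.numeric, logical(1))
  m <- colMeans(rows[, num, drop = FALSE])
  list(mean = m, rounded = roundHalfUp(m))
}

#' Published benchmark scores of the method
#'
#' Per-case residue-level results of plain MimoPro and of the
#' pruning+mimotope method on the standard 18-complex phage-display
#' benchmark, as published (2-decimal values).
#'
#' @return data.frame, one row per benchmark case.
#' @export
benchmarkScores <- function() {
  read.table(system.file("extdata", "benchmark_scores.tsv",
                         package = "mimoprune"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#")
}

#' The vascular endothelial growth factor worked example
#'
#' The published residue lists for VEGF (PDB 1BJ1, chain W): the
#' crystallographic epitope (19 residues), the MimoPro candidate-epitope
#' prediction (32 residues) and the 15 residues removed by the pruning
#' step, parsed via \code{\link{parseResidueList}}.
#'
#' @return list of data.frames \code{epitope}, \code{predicted},
#'   \code{removed}.
#' @export
vegfWorkedExample <- function() {
  lines <- readLines(system.file("extdata", "vegf_worked_example.txt",
                                 package = "mimoprune"), warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  get <- function(tag) {
    ln <- lines[startsWith(lines, paste0(tag, ":"))]
    parseResidueList(sub("^[a-z]+:\\s*", "", ln))
  }
  list(epitope = get("epitope"), predicted = get("predicted"),
       removed = get("removed"))
}
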