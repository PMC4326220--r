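# Imbalance-corrected classification of surface residues. The training data
# of this problem run roughly eight nonepitope residues per epitope residue,
# so each member forest sees all positives plus an equally sized
# without-replacement draw of negatives, and the ensemble decision is a
# majority vote over members (ties keep the residue: a wrongly pruned
# epitope residue is unrecoverable downstream).

#' Draw class-balanced training subsets
#'
#' Each subset contains every positive row plus a without-replacement random
#' sample of negatives of equal size; subsets differ only in their negative
#' draws and are fully determined by \code{seed}.
#'
#' @param table data.frame of feature columns plus a binary \code{label}
#'   column (1 = epitope).
#' @param n number of subsets.
#' @param seed integer seed.
#' @return list of \code{n} data.frames.
#' @export
balancedSubsets <- function(table, n = 10, seed = 1) {
  stopifnot("label" %in% colnames(table))
  pos <- which(table$label == 1)
  neg <- which(table$label == 0)
  if (length(pos) == 0L) stop("cannot balance: no positive rows")
  if (length(neg) < length(pos))
    stop("cannot balance: fewer negatives (", length(neg),
         ") than positives (", length(pos), ")")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    table[c(pos, sample(neg, length(pos))), , drop = FALSE]
  })
}

#' Train the balanced random-forest voting ensemble
#'
#' Fits one random forest per balanced subset. The defaults mirror the
#' selected classifier configuration: 5 trees per forest, the "auto" number
#' of features per split (\code{floor(log2(M) + 1)} for M features), seed 1.
#'
#' @param table labelled feature table (see \code{\link{balancedSubsets}}).
#' @param n number of balanced subsets / member forests.
#' @param trees trees per forest.
#' @param featuresPerSplit variables tried per split; \code{NULL} = auto.
#' @param seed integer seed controlling subsets and forest fits.
#' @return an \linkS4class{EpitopeEnsemble}.
#' @export
trainEnsemble <- function(table, n = 10, trees = 5,
                          featuresPerSplit = NULL, seed = 1) {
  featNames <- setdiff(colnames(table), "label")
  M <- length(featNames)
  if (is.null(featuresPerSplit))
    featuresPerSplit <- max(1L, as.integer(floor(log2(M) + 1)))
  vars <- vapply(table[featNames], function(col) stats::var(col), numeric(1))
  if (all(vars == 0))
    warning("all features have zero variance; model will be uninformative")
  subsets <- balancedSubsets(table, n = n, seed = seed)
  members <- lapply(seq_len(n), function(i) {
    sub <- subsets[[i]]
    set.seed(seed * 10000L + i)
    randomForest::randomForest(
      x = sub[, featNames, drop = FALSE],
      y = factor(sub$label, levels = c(0, 1)),
      ntree = trees, mtry = min(featuresPerSplit, M))
  })
  new("EpitopeEnsemble", members = members, nMembers = as.integer(n),
      treesPerForest = as.integer(trees),
      featuresPerSplit = as.integer(featuresPerSplit),
      seed = as.integer(seed), featureNames = featNames)
}

#' Classify surface residues by ensemble vote
#'
#' Each member forest casts one vote per residue; the residue is kept
#' ("epitope") when positive votes reach at least half the ensemble
#' (ties keep).
#'
#' @param model an \linkS4class{EpitopeEnsemble}.
#' @param features feature table with rownames = residue keys and the
#'   training columns.
#' @return a \linkS4class{PrunedSurface}.
#' @export
classifySurface <- function(model, features) {
  missing <- setdiff(model@featureNames, colnames(features))
  extra <- setdiff(colnames(features), model@featureNames)
  if (length(missing) || length(extra))
    stop("feature columns do not match training columns; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  x <- features[, model@featureNames, drop = FALSE]
  votes <- Reduce(`+`, lapply(model@members, function(rf) {
    as.integer(predict(rf, x) == "1")
  }))
  votes <- setNames(as.integer(votes), rownames(features))
  kept <- names(votes)[2L * votes >= model@nMembers]
  new("PrunedSurface", kept = kept,
      removed = setdiff(names(votes), kept),
      votes = votes, nMembers = model@nMembers)
}

#' Restrict a surface to the residues the ensemble kept
#'
#' @param surface the \linkS4class{SurfaceSet} the classification was made on.
#' @param pruned the \linkS4class{PrunedSurface}.
#' @return a new \linkS4class{SurfaceSet} containing only kept residues; the
#'   input is untouched.
#' @export
pruneSurface <- function(surface, pruned) {
  all_ids <- union(pruned@kept, pruned@removed)
  if (!setequal(all_ids, surface@residues))
    stop("pruned partition does not match this surface")
  kept <- surface@residues[surface@residues %in% pruned@kept]
  message("pruning removed ", length(pruned@removed), " of ",
          length(surface@residues), " surface residues")
  out <- surface
  out@residues <- kept
  out@epitope <- intersect(surface@epitope, kept)
  out@flags <- c(surface@flags,
                 paste0("pruned:", length(pruned@removed)))
  out
}

#' Serialize / restore an ensemble as a portable JSON descriptor
#'
#' Trees are exported split-by-split (variable, threshold, children, leaf
#' class) so a model survives R and randomForest version changes; prediction
#' from a restored model walks the exported trees directly.
#'
#' @param model an \linkS4class{EpitopeEnsemble}.
#' @param path JSON file path.
#' @return \code{writeEnsembleJSON}: the path, invisibly;
#'   \code{readEnsembleJSON}: a list-based model usable by
#'   \code{\link{classifySurface}}.
#' @export
writeEnsembleJSON <- function(model, path) {
  desc <- list(
    n_members = model@nMembers, trees_per_forest = model@treesPerForest,
    features_per_split = model@featuresPerSplit, seed = model@seed,
    feature_names = model@featureNames,
    members = lapply(model@members, function(rf) {
      lapply(seq_len(rf$ntree), function(k) {
        tr <- randomForest::getTree(rf, k, labelVar = FALSE)
        list(left = tr[, "left daughter"], right = tr[, "right daughter"],
             var = tr[, "split var"], point = tr[, "split point"],
             status = tr[, "status"], pred = tr[, "prediction"])
      })
    }))
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.predictExportedTree <- function(tree, x) {
  # x: numeric matrix, columns in training order; returns class 0/1 per row
  apply(x, 1, function(row) {
    node <- 1L
    while (tree$status[node] != -1L) {
      node <- if (row[tree$var[node]] <= tree$point[node])
        tree$left[node] else tree$right[node]
    }
    tree$pred[node] - 1L  # getTree codes classes 1/2 for levels 0/1
  })
}

#' @rdname writeEnsembleJSON
#' @param x restored model object (class \code{ensembleJSON}) or matrix.
#' @export
readEnsembleJSON <- function(path) {
  desc <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  structure(desc, class = "ensembleJSON")
}

#' Classify a feature table with a JSON-restored ensemble
#'
#' @param model an object from \code{\link{readEnsembleJSON}}.
#' @param features feature table, rownames = residue keys.
#' @return a \linkS4class{PrunedSurface}.
#' @export
classifySurfaceJSON <- function(model, features) {
  missing <- setdiff(model$feature_names, colnames(features))
  extra <- setdiff(colnames(features), model$feature_names)
  if (length(missing) || length(extra))
    stop("feature columns do not match training columns; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  votes <- rep(0L, nrow(x))
  for (member in model$members) {
    treeVotes <- matrix(0L, nrow(x), length(member))
    for (k in seq_along(member))
      treeVotes[, k] <- .predictExportedTree(member[[k]], x)
    votes <- votes + as.integer(rowMeans(treeVotes) > 0.5)
  }
  votes <- setNames(votes, rownames(features))
  kept <- names(votes)[2L * votes >= model$n_members]
  new("PrunedSurface", kept = kept,
      removed = setdiff(names(votes), kept),
      votes = votes, nMembers = as.integer(model$n_members))
}
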