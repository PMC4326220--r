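test_that("balanced subsets hold all positives plus equal negative draws", {
  tab <- syntheticLabelledTable(nPositives = 3, ratio = 8, shift = 1,
                                seed = 4)
  subs <- balancedSubsets(tab, n = 5, seed = 2)
  expect_length(subs, 5)
  for (s in subs) {
    expect_equal(nrow(s), 6)
    expect_equal(sum(s$label == 1), 3)
    expect_equal(sum(s$label == 0), 3)
    expect_true(all(rownames(tab)[tab$label == 1] %in% rownames(s)))
    expect_false(anyDuplicated(rownames(s)) > 0)
  }

  # already balanced: every subset contains all rows
  eq <- tab[c(which(tab$label == 1), which(tab$label == 0)[1:3]), ]
  for (s in balancedSubsets(eq, n = 3, seed = 1))
    expect_setequal(rownames(s), rownames(eq))

  # determinism
  expect_identical(balancedSubsets(tab, n = 4, seed = 9),
                   balancedSubsets(tab, n = 4, seed = 9))
  expect_false(identical(balancedSubsets(tab, n = 4, seed = 9),
                         balancedSubsets(tab, n = 4, seed = 10)))

  # fewer negatives than positives cannot be balanced
  flipped <- tab
  flipped$label <- 1 - flipped$label
  expect_error(balancedSubsets(flipped, n = 2, seed = 1), "cannot balance")
})

test_that("a separable table trains to perfect training votes", {
  # 6-sigma shift: the classes are linearly separable for all practical
  # purposes, so the training-set vote must be exact
  tab <- syntheticLabelledTable(nPositives = 15, ratio = 4, shift = 6,
                                seed = 11)
  model <- trainEnsemble(tab, n = 5, trees = 5, seed = 1)
  expect_s4_class(model, "EpitopeEnsemble")
  expect_equal(model@featuresPerSplit, 4L)  # floor(log2(8) + 1)

  feats <- tab[, setdiff(colnames(tab), "label")]
  pruned <- classifySurface(model, feats)
  keptLabels <- tab[keptResidues(pruned), "label"]
  removedLabels <- tab[removedResidues(pruned), "label"]
  expect_true(all(keptLabels == 1))
  expect_true(all(removedLabels == 0))

  # the partition is exact and votes are recorded for every residue
  expect_setequal(union(keptResidues(pruned), removedResidues(pruned)),
                  rownames(tab))
  expect_length(intersect(keptResidues(pruned), removedResidues(pruned)), 0)
  expect_length(pruned@votes, nrow(tab))

  # determinism: same seed, same model decisions
  model2 <- trainEnsemble(tab, n = 5, trees = 5, seed = 1)
  pruned2 <- classifySurface(model2, feats)
  expect_identical(pruned@votes, pruned2@votes)
})

test_that("an n = 1 ensemble is a single balanced forest", {
  tab <- syntheticLabelledTable(nPositives = 10, ratio = 3, shift = 2,
                                seed = 3)
  model <- trainEnsemble(tab, n = 1, trees = 9, seed = 5)
  expect_equal(model@nMembers, 1L)
  feats <- tab[, setdiff(colnames(tab), "label")]
  pruned <- classifySurface(model, feats)
  single <- as.integer(predict(model@members[[1]], feats) == "1")
  expect_equal(unname(pruned@votes), single)
  # with one member, vote >= n/2 means the forest's own call
  expect_setequal(keptResidues(pruned), rownames(feats)[single == 1])
})

test_that("shuffled labels give chance-level held-out accuracy", {
  tab <- syntheticLabelledTable(nPositives = 40, ratio = 3, shift = 3,
                                seed = 21)
  set.seed(33)
  tab$label <- sample(tab$label)
  train <- tab[seq(1, nrow(tab), by = 2), ]
  test <- tab[seq(2, nrow(tab), by = 2), ]
  model <- trainEnsemble(train, n = 5, trees = 5, seed = 1)
  pruned <- classifySurface(model, test[, setdiff(colnames(test), "label")])
  pred <- as.integer(rownames(test) %in% keptResidues(pruned))
  bacc <- (mean(pred[test$label == 1] == 1) +
           mean(pred[test$label == 0] == 0)) / 2
  expect_gt(bacc, 0.3)
  expect_lt(bacc, 0.7)
})

test_that("vote ties resolve toward keeping the residue", {
  # two hand-written single-leaf trees: one always votes epitope, one never
  leafTree <- function(class) {
    list(left = 0L, right = 0L, var = 0L, point = 0,
         status = -1L, pred = class)
  }
  desc <- list(n_members = 2, trees_per_forest = 1, features_per_split = 1,
               seed = 1, feature_names = c("f1", "f2"),
               members = list(list(leafTree(2L)), list(leafTree(1L))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
  model <- readEnsembleJSON(path)
  feats <- data.frame(f1 = c(0, 1), f2 = c(1, 0),
                      row.names = c("A:1", "A:2"))
  pruned <- classifySurfaceJSON(model, feats)
  expect_equal(unname(pruned@votes), c(1L, 1L))  # split 1-1 vote
  expect_setequal(keptResidues(pruned), c("A:1", "A:2"))
})

test_that("JSON serialization round-trips the ensemble decisions", {
  tab <- syntheticLabelledTable(nPositives = 12, ratio = 4, shift = 2,
                                seed = 8)
  feats <- tab[, setdiff(colnames(tab), "label")]
  model <- trainEnsemble(tab, n = 3, trees = 5, seed = 2)
  direct <- classifySurface(model, feats)

  path <- tempfile(fileext = ".json")
  writeEnsembleJSON(model, path)
  restored <- readEnsembleJSON(path)
  viaJson <- classifySurfaceJSON(restored, feats)

  expect_identical(viaJson@votes, direct@votes)
  expect_setequal(keptResidues(viaJson), keptResidues(direct))
})

test_that("classification refuses mismatched feature columns", {
  tab <- syntheticLabelledTable(nPositives = 5, ratio = 2, shift = 2,
                                seed = 6)
  model <- trainEnsemble(tab, n = 2, trees = 3, seed = 1)
  bad <- tab[, setdiff(colnames(tab), c("label", "planarity"))]
  bad$bogus <- 1
  expect_error(classifySurface(model, bad), "missing: \\[planarity\\]")
  expect_error(classifySurface(model, bad), "extra: \\[bogus\\]")
})

test_that("pruning partitions the surface and leaves the input untouched", {
  case <- syntheticAntigen(nResidues = 32, fold = "blob", epitopeSize = 6,
                           seed = 13)
  surf <- case$surface
  keys <- surfaceResidues(surf)

  # nothing removed
  none <- new("PrunedSurface", kept = keys, removed = character(0),
              votes = setNames(rep(1L, length(keys)), keys), nMembers = 1L)
  expect_equal(surfaceResidues(suppressMessages(pruneSurface(surf, none))),
               keys)

  # 15 removed from the toy surface -> the arithmetic remainder kept,
  # chain order preserved
  rm15 <- sample(keys, 15)
  part <- new("PrunedSurface", kept = setdiff(keys, rm15), removed = rm15,
              votes = setNames(rep(0L, length(keys)), keys), nMembers = 1L)
  kept <- suppressMessages(pruneSurface(surf, part))
  expect_equal(length(surfaceResidues(kept)), length(keys) - 15)
  expect_equal(surfaceResidues(kept), keys[!(keys %in% rm15)])
  expect_equal(surfaceResidues(surf), keys)  # untouched

  # everything removed -> empty surface -> downstream "no prediction"
  all <- new("PrunedSurface", kept = character(0), removed = keys,
             votes = setNames(rep(0L, length(keys)), keys), nMembers = 1L)
  empty <- suppressMessages(pruneSurface(surf, all))
  expect_length(surfaceResidues(empty), 0)
  scored <- scorePatches(buildPatchGraphs(empty), c("ACDEF"))
  expect_equal(nrow(scored$ranking), 0)
  expect_length(predictedResidues(predictEpitope(scored)), 0)

  # identifier mismatch is an error
  alien <- new("PrunedSurface", kept = c("Z:1"), removed = c("Z:2"),
               votes = c("Z:1" = 1L, "Z:2" = 0L), nMembers = 1L)
  expect_error(pruneSurface(surf, alien), "does not match")
})

test_that("well-separated classes are recovered on held-out data", {
  tab <- syntheticLabelledTable(nPositives = 40, ratio = 3, shift = 2,
                                nShift = 2, seed = 17)
  train <- tab[seq(1, nrow(tab), by = 2), ]
  test <- tab[seq(2, nrow(tab), by = 2), ]
  model <- trainEnsemble(train, n = 10, trees = 5, seed = 1)
  pruned <- classifySurface(model, test[, setdiff(colnames(test), "label")])
  pred <- as.integer(rownames(test) %in% keptResidues(pruned))
  bacc <- (mean(pred[test$label == 1] == 1) +
           mean(pred[test$label == 0] == 0)) / 2
  expect_gt(bacc, 0.85)
})
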