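test_that("mimotope files parse from FASTA and plain text", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDEFGHIK", ">p2", "acdefghik", ">p3", "WYVKLMNPQ",
               ">p4", "AAAAAAAAA", ">p5", "KKKKKKKKK", ">p6", "MNPQRSTVW"),
             fa)
  peps <- readMimotopes(fa)
  expect_length(peps, 6)
  expect_true(all(Biostrings::width(peps) == 9))
  expect_equal(as.character(peps)[[2]], "ACDEFGHIK")  # uppercased

  txt <- tempfile(fileext = ".txt")
  writeLines(c("ACDK", "wyvk"), txt)
  expect_equal(as.character(readMimotopes(txt)), c("ACDK", "WYVK"))

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(readMimotopes(empty), "no mimotopes")

  bad <- tempfile()
  writeLines("ACDB1", bad)
  expect_error(readMimotopes(bad), "non-amino-acid")
})

test_that("a path graph spelling the peptide aligns perfectly", {
  g <- makePathGraph(strsplit("ACDEF", "")[[1]])
  aln <- alignPeptideToGraph(g, "ACDEF", matrix = identityMatrix(),
                             gapPenalty = -1, maxSkips = 0)
  expect_true(aln$complete)
  expect_equal(aln$score, 5)
  expect_equal(aln$path, patchMembers(g))
})

test_that("a single-vertex graph yields a flagged partial alignment", {
  g <- makePathGraph("A")
  aln <- alignPeptideToGraph(g, "AAA", matrix = identityMatrix(),
                             gapPenalty = -1, maxSkips = 0)
  expect_false(aln$complete)
  expect_equal(aln$matched, 1)
  expect_equal(aln$score, 1 + (-1) * 2)  # one match, two forced gaps
})

test_that("search equals exhaustive enumeration on random small graphs", {
  blosum <- substitutionMatrix("BLOSUM62")
  set.seed(101)
  worse <- 0
  for (i in 1:120) {
    nV <- sample(3:8, 1)
    fx <- randomGraphFixture(nV, pEdge = runif(1, 0.2, 0.8))
    L <- sample(3:5, 1)
    pep <- paste(sample(mimoprune:::.AA_LETTERS, L, replace = TRUE),
                 collapse = "")
    maxSkips <- sample(0:2, 1)
    useBlosum <- i %% 2 == 0
    m <- if (useBlosum) blosum[mimoprune:::.AA_LETTERS,
                               mimoprune:::.AA_LETTERS] else
      identityMatrix(2, -1)
    gap <- if (useBlosum) -4 else -1

    g <- makeGraph(fx$aa, fx$edges)
    got <- alignPeptideToGraph(g, pep, matrix = m, gapPenalty = gap,
                               maxSkips = maxSkips)
    oracle <- oracleAlign(fx$aa, fx$edges, pep, m, gap, maxSkips)
    if (oracle$found) {
      expect_true(got$complete)
      expect_equal(got$score, oracle$score, tolerance = 1e-9)
      if (got$expansions >= oracle$nodes) worse <- worse + 1
    } else {
      # peptide longer than any simple path plus allowed skips
      expect_false(got$complete)
    }
  }
  # pruning must be doing real work on the vast majority of instances
  expect_lt(worse, 12)
})

test_that("the reported path actually attains the reported score", {
  set.seed(77)
  m <- substitutionMatrix("BLOSUM62")
  for (i in 1:20) {
    fx <- randomGraphFixture(7, pEdge = 0.5)
    g <- makeGraph(fx$aa, fx$edges)
    pep <- paste(sample(mimoprune:::.AA_LETTERS, 4, replace = TRUE),
                 collapse = "")
    aln <- alignPeptideToGraph(g, pep, matrix = m, gapPenalty = -4,
                               maxSkips = 2)
    expect_true(aln$complete)
    # vertices distinct, consecutive ones adjacent
    idx <- match(aln$path, patchMembers(g))
    expect_false(anyDuplicated(idx) > 0)
    if (length(idx) > 1) {
      eset <- paste(pmin(g@edges[, 1], g@edges[, 2]),
                    pmax(g@edges[, 1], g@edges[, 2]))
      steps <- paste(pmin(head(idx, -1), idx[-1]),
                     pmax(head(idx, -1), idx[-1]))
      expect_true(all(steps %in% eset))
    }
    # recompute the score from the path and skip count
    pepChars <- strsplit(pep, "")[[1]]
    best <- -Inf
    L <- length(pepChars); k <- length(idx)
    skipSets <- combn(L, L - k, simplify = FALSE)
    if (L == k) skipSets <- list(integer(0))
    for (S in skipSets) {
      keep <- setdiff(seq_len(L), S)
      sc <- sum(m[cbind(pepChars[keep], g@aa[idx])]) - 4 * length(S)
      best <- max(best, sc)
    }
    expect_equal(aln$score, best, tolerance = 1e-9)
  }
})

test_that("Gumbel fitting recovers known parameters and flags degeneracy", {
  set.seed(9)
  u <- runif(1e5)
  sample_gumbel <- -log(-log(u))  # Gumbel(0, 1)
  fit <- gumbelFit(sample_gumbel)
  expect_lt(abs(fit$mu), 0.05)
  expect_lt(abs(fit$beta - 1), 0.05)

  const <- gumbelFit(rep(3.5, 500))
  expect_equal(const$beta, 1e-6)
  expect_equal(const$mu, 3.5, tolerance = 1e-5)
  expect_equal(const$flags, "degenerate null")
})

test_that("EVD calibration on a graph is seed-deterministic", {
  g <- makePathGraph(strsplit("ACDEFGHIKL", "")[[1]])
  c1 <- calibrateEVD(g, 4, nSamples = 300, seed = 5)
  c2 <- calibrateEVD(g, 4, nSamples = 300, seed = 5)
  c3 <- calibrateEVD(g, 4, nSamples = 300, seed = 6)
  expect_identical(c1, c2)
  expect_false(identical(c1$mu, c3$mu))
  expect_gt(c1$beta, 0)
})

test_that("P-values obey the closed form and its limits", {
  cal <- list(mu = 2, beta = 0.7)
  expect_equal(evdPValue(2, cal), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(evdPValue(2 + 0.7 * log(1 / log(2)), cal), 0.5,
               tolerance = 1e-12)
  xs <- seq(-5, 40, by = 0.5)
  ps <- evdPValue(xs, cal)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1e-300 & ps <= 1))
  expect_lt(evdPValue(1e4, cal), 1e-200)
})

test_that("P-values are uniform when the null really is Gumbel", {
  # the full transform chain (fit -> closed-form P) yields uniform
  # P-values on fresh draws from the fitted family
  set.seed(15)
  train <- 4 - 1.7 * log(-log(runif(2000)))   # Gumbel(4, 1.7)
  fit <- gumbelFit(train)
  fresh <- 4 - 1.7 * log(-log(runif(1000)))
  ks <- suppressWarnings(stats::ks.test(evdPValue(fresh, fit), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("graph-null P-values are near-uniform up to the Gumbel
           approximation error", {
  # Best alignment scores over a patch graph are maxima of correlated
  # integer-valued path sums: the Gumbel family is an approximation of
  # that null, not its exact law. Here the approximation error is
  # quantified: the continuity-corrected PIT of a fresh graph null stays
  # within a documented sup-norm bound of uniform.
  g <- makePathGraph(strsplit("ACDEFGHIKLMNPQRS", "")[[1]])
  cal <- calibrateEVD(g, 5, nSamples = 2000, seed = 11)
  sm <- mimoprune:::.scoreMatrix(substitutionMatrix("BLOSUM62"))
  null <- mimoprune:::.calibrateScoresCpp(
    g@edges, mimoprune:::.aaIndex(g@aa), length(patchMembers(g)), 5L,
    sm, -4, 2L, 1000L, 999L, 20L)
  set.seed(1)
  ps <- evdPValue(null + runif(1000, -0.5, 0.5), cal)
  D <- suppressWarnings(stats::ks.test(ps, "punif"))$statistic
  expect_lt(unname(D), 0.12)
  # and the transform is at least correctly centred: median P near 0.5
  expect_lt(abs(stats::median(ps) - 0.5), 0.1)
})

test_that("patch scoring ranks a planted exact-match patch first", {
  planted <- makePathGraph(strsplit("WWCCHHMM", "")[[1]], chain = "A")
  decoy <- makePathGraph(strsplit("AAAAGGGG", "")[[1]], chain = "B")
  mims <- c("WWCCHH", "WCCHHM", "CCHHMM")
  scored <- scorePatches(list(decoy, planted), mims, nSamples = 300,
                         seed = 3)
  expect_equal(scored$ranking$center[1], planted@center)

  # single patch is trivially first
  one <- scorePatches(list(planted), mims, nSamples = 300, seed = 3)
  expect_equal(nrow(one$ranking), 1)

  # identical duplicate patches: identical scores, deterministic tie-break
  dup <- makePathGraph(strsplit("WWCCHHMM", "")[[1]], chain = "C")
  tie <- scorePatches(list(dup, planted), mims, nSamples = 300, seed = 3)
  expect_equal(tie$ranking$score[1], tie$ranking$score[2], tolerance = 1e-9)
  expect_equal(tie$ranking$center, c("A:1", "C:1"))  # id-order tie-break
})

test_that("ranking ignores mimotope order and uniform duplication", {
  planted <- makePathGraph(strsplit("WWCCHHMM", "")[[1]], chain = "A")
  decoy <- makePathGraph(strsplit("KKEEDDRR", "")[[1]], chain = "B")
  mims <- c("WWCCHH", "CCHHMM", "WCCHHM")
  base <- scorePatches(list(planted, decoy), mims, nSamples = 200, seed = 2)
  perm <- scorePatches(list(planted, decoy), rev(mims), nSamples = 200,
                       seed = 2)
  expect_equal(base$ranking, perm$ranking, tolerance = 1e-9)

  dup <- scorePatches(list(planted, decoy), rep(mims, each = 3),
                      nSamples = 200, seed = 2)
  expect_equal(dup$ranking$center, base$ranking$center)
  expect_equal(dup$ranking$score, 3 * base$ranking$score, tolerance = 1e-9)
})

test_that("prediction modes select patch members or path unions", {
  planted <- makePathGraph(strsplit("WWCCHHMM", "")[[1]])
  mims <- rep("WWCCHH", 3)
  scored <- scorePatches(list(planted), mims, nSamples = 200, seed = 4)

  patchMode <- predictEpitope(scored, mode = "patch")
  expect_setequal(predictedResidues(patchMode), patchMembers(planted))

  pathMode <- predictEpitope(scored, mode = "paths")
  expect_equal(sort(predictedResidues(pathMode)),
               sort(patchMembers(planted)[1:6]))

  # empty ranking: a no-prediction object
  none <- structure(list(ranking = data.frame(center = character(0),
                                              score = numeric(0),
                                              n_members = integer(0)),
                         graphs = list(), alignments = list()),
                    class = "patchScores")
  expect_length(predictedResidues(predictEpitope(none)), 0)
})
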