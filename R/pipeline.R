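# One-command end-to-end run: surface -> features -> prune -> patches ->
# align -> predict (-> evaluate), with stage logging and a reproducibility
# manifest.

#' Default run configuration
#'
#' All tunables of the pipeline with their defaults: 5\% side-chain RSA
#' surface cutoff with a 1.4 A probe, 1 A^2 ASA-loss epitope definition,
#' ensemble of 10 balanced forests with 5 trees each (seed 1), 12 A patch
#' radius, compactness target 0.35 with the ADT searched over 4-9 A in
#' 0.5 A steps, BLOSUM62 with gap penalty -4 and at most 2 skips, 1000
#' extreme-value calibration samples, and whole-patch prediction mode.
#'
#' @return named list of configuration values.
#' @export
defaultConfig <- function() {
  list(rsa_threshold = 0.05, probe = 1.4, delta_asa = 1.0,
       asa_points = 960, feature_radius = 10,
       n_subsets = 10, trees = 5, features_per_split = NA,
       seed = 1, patch_radius = 12, cf_target = 0.35,
       adt_min = 4, adt_max = 9, adt_step = 0.5,
       matrix = "BLOSUM62", gap_penalty = -4, max_skips = 2,
       evd_samples = 1000, mode = "patch")
}

#' Run the full epitope-prediction pipeline
#'
#' Stages: read/accept the antigen, extract the surface, build features,
#' classify and prune (unless \code{prune = FALSE} or no model is given,
#' which reproduces the plain patch-search behaviour), build patch graphs,
#' score them against the mimotopes, predict, and — when ground truth is
#' available — evaluate. Counts are logged per stage via \code{message()}.
#'
#' @param pdb path to a PDB file, or an \linkS4class{AntigenStructure}.
#' @param chain antigen chain id (ignored when \code{pdb} is a structure).
#' @param mimotopes path to a FASTA/line-per-peptide file, or an
#'   \code{AAStringSet}/character vector.
#' @param model an \linkS4class{EpitopeEnsemble}, a path to an ensemble
#'   JSON, or NULL (no pruning).
#' @param truth optional ground truth: a residue-list string such as
#'   "I80 M81 ...", a character vector of residue keys, or NULL to use the
#'   epitope annotated on the surface (e.g. from partner chains).
#' @param partners optional partner chain ids for epitope annotation.
#' @param prune logical; \code{FALSE} skips the pruning stage.
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param outdir optional directory for stage artifacts (TSVs + manifest).
#' @return list with \code{prediction} (\linkS4class{EpitopePrediction}),
#'   \code{status} ("prediction made" / "no prediction"), \code{evaluation}
#'   (or NULL), \code{counts} (per-stage sizes), \code{config},
#'   \code{manifest}.
#' @export
runPipeline <- function(pdb, chain = NULL, mimotopes, model = NULL,
                        truth = NULL, partners = NULL, prune = !is.null(model),
                        config = defaultConfig(), outdir = NULL) {
  cfg <- utils::modifyList(defaultConfig(), config)
  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("mimoprune")))

  if (is(pdb, "AntigenStructure")) {
    structure <- pdb
    manifest$pdb <- structure@pdbId
  } else {
    structure <- readPdb(pdb, chain, partnerChains = partners,
                         probeRadius = cfg$probe)
    manifest$pdb <- unname(tools::md5sum(pdb))
  }
  if (is.character(mimotopes) && base::length(mimotopes) == 1 &&
      file.exists(mimotopes)) {
    manifest$mimotopes <- unname(tools::md5sum(mimotopes))
    mimotopes <- readMimotopes(mimotopes)
  }
  peps <- as.character(mimotopes)
  message("stage input: ", nrow(structure@residues), " antigen residues, ",
          base::length(peps), " mimotopes")

  surface <- if (base::length(structure@partnerChains) > 0) {
    annotateEpitope(structure, deltaAsaThreshold = cfg$delta_asa,
                    rsaThreshold = cfg$rsa_threshold,
                    nPoints = cfg$asa_points)
  } else {
    extractSurface(structure, rsaThreshold = cfg$rsa_threshold,
                   nPoints = cfg$asa_points)
  }
  message("stage surface: ", base::length(surface@residues),
          " surface residues")
  counts <- list(residues = nrow(structure@residues),
                 surface = base::length(surface@residues))

  searchSurface <- surface
  if (isTRUE(prune)) {
    if (is.null(model))
      stop("stage prune: pruning requested but no model supplied")
    if (is.character(model)) model <- readEnsembleJSON(model)
    feats <- buildFeatureTable(surface, radius = cfg$feature_radius)
    pruned <- if (is(model, "EpitopeEnsemble"))
      classifySurface(model, feats) else classifySurfaceJSON(model, feats)
    searchSurface <- pruneSurface(surface, pruned)
    counts$removed <- base::length(pruned@removed)
    counts$kept <- base::length(pruned@kept)
  } else {
    counts$removed <- 0L
    counts$kept <- base::length(surface@residues)
  }

  graphs <- buildPatchGraphs(searchSurface, radius = cfg$patch_radius,
                             cfTarget = cfg$cf_target, adtMin = cfg$adt_min,
                             adtMax = cfg$adt_max, step = cfg$adt_step)
  counts$patches <- base::length(graphs)
  message("stage patches: ", base::length(graphs), " patch graphs")

  scored <- scorePatches(graphs, peps,
                         matrix = substitutionMatrix(cfg$matrix),
                         gapPenalty = cfg$gap_penalty,
                         maxSkips = cfg$max_skips,
                         nSamples = cfg$evd_samples, seed = cfg$seed)
  prediction <- predictEpitope(scored, mode = cfg$mode)
  status <- if (base::length(prediction@predicted) == 0)
    "no prediction" else "prediction made"
  counts$winning_score <- prediction@score
  message("stage predict: ", status, " (",
          base::length(prediction@predicted), " residues)")

  evaluation <- NULL
  truthKeys <- NULL
  if (!is.null(truth)) {
    truthKeys <- if (base::length(truth) == 1 && grepl("[0-9]", truth) &&
                     !all(truth %in% surface@table$key)) {
      lst <- parseResidueList(truth)
      surface@table$key[surface@table$resno %in% lst$resno]
    } else truth
  } else if (base::length(surface@epitope) > 0) {
    truthKeys <- surface@epitope
  }
  if (!is.null(truthKeys) && base::length(truthKeys) > 0) {
    evalSurface <- surface
    evalSurface@epitope <- intersect(union(surface@epitope, truthKeys),
                                     surface@residues)
    if (base::length(evalSurface@epitope) == 0)
      evalSurface@epitope <- truthKeys[truthKeys %in% surface@residues]
    evaluation <- evaluateCase(prediction, evalSurface)
  }

  out <- list(prediction = prediction, status = status,
              evaluation = evaluation, counts = counts, config = cfg,
              manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tab <- surface@table
    tab$predicted <- tab$key %in% prediction@predicted
    write.table(tab, file.path(outdir, "surface.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(paste(prediction@predicted, collapse = " "),
               file.path(outdir, "predicted.txt"))
  }
  out
}
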