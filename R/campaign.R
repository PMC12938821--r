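#' @include synthkit.R neighborhood.R landscape.R bo.R
NULL

#' Campaign configuration
#'
#' Builds the configuration for an end-to-end generative campaign
#' (library -> filters -> autoencoder -> KAL -> clustering -> local
#' sampling -> optional Bayesian optimization -> report). Accepts a YAML
#' file path or a nested list; unspecified fields take desk-scale
#' defaults. A single global seed fans out to per-stage seeds through
#' \code{\link{spawnSeed}}, so stages are individually reproducible.
#'
#' @param config YAML path or nested list of overrides.
#' @param seed optional global seed override.
#' @return object of class \code{campaignConfig}.
#' @export
campaignConfig <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    seed = 1L,
    targetFamily = "SRC",
    library = list(source = "synthetic", path = NULL, familyN = 60L,
                   backgroundN = 240L),
    vae = list(latentDim = 16L, hiddenDim = 96L, epochs = 400L,
               lr = 2e-3, klWeightMax = 0.05),
    kal = list(ntree = 500L, folds = 5L, backgroundN = NULL,
               multiclass = TRUE),
    cluster = list(k = 3L, selectK = FALSE, candidateKs = 2:5),
    remodel = list(s = 0.8, noiseSd = 5.0, noiseMode = "absolute",
                   kalThreshold = 0.7, tanimotoThreshold = 0.75,
                   maxAttempts = 500L, temperature = 1.0,
                   minSmilesLength = 10L),
    bo = list(enabled = FALSE, mode = "unbiased", nInitRandom = 15L,
              nSeeded = 20L, maxSteps = 40L, plateauWindow = 100L,
              plateauTol = 0.001, refitPeriod = 10L, eiJitter = 0.01,
              acqRestarts = 5L),
    report = list(kalThreshold = 0.5, similarityThreshold = 0.75))
  merged <- utils::modifyList(def, config)
  if (!is.null(seed)) merged$seed <- as.integer(seed)
  structure(merged, class = "campaignConfig")
}

.writeCsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run an end-to-end generative campaign
#'
#' Executes the configured stages in order, writing models' summaries,
#' ledgers, the generated-set CSV, reports and a manifest recording every
#' stage seed and parameter into \code{outDir}. Re-running with the same
#' configuration reproduces identical outputs. A stage failure halts the
#' campaign with the stage name; artifacts written so far are left in
#' place.
#'
#' @param config a \code{\link{campaignConfig}} (or list/YAML path
#'   coerced to one).
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the fitted objects, reports and file
#'   paths.
#' @export
runCampaign <- function(config = campaignConfig(), outDir = "campaign_out") {
  if (!inherits(config, "campaignConfig")) config <- campaignConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- sapply(c("library", "vae", "kal", "cluster", "remodel", "bo"),
                  function(s) spawnSeed(config$seed, s))
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("campaign stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  lib <- stage("library", {
    if (identical(config$library$source, "synthetic")) {
      generateToyLibrary(defaultLibrarySpec(
        seed = seeds[["library"]],
        familyN = config$library$familyN,
        backgroundN = config$library$backgroundN))
    } else {
      if (!file.exists(config$library$path %||% "")) {
        stop(sprintf("library path not found: '%s'", config$library$path))
      }
      standardizeMolecules(readMoleculeCsv(config$library$path))$molecules
    }
  })

  filt <- stage("filters", applyLibraryFilters(lib))
  lib <- filt$retained
  paths$library <- .writeCsv(as.data.frame(lib), outDir, "library.csv")
  paths$filterReport <- .writeCsv(filt$report, outDir, "filter_report.csv")

  vae <- stage("vae", trainVae(
    lib, latentDim = config$vae$latentDim,
    hiddenDim = config$vae$hiddenDim, epochs = config$vae$epochs,
    lr = config$vae$lr, klWeightMax = config$vae$klWeightMax,
    seed = seeds[["vae"]]))
  paths$vaeLog <- .writeCsv(vae@trainingLog, outDir, "vae_training_log.csv")

  Z <- encodeLatent(vae, lib)
  fam <- molFamily(lib)
  isBg <- fam == "background"
  stats <- stage("landscape", familyLatentStats(Z, fam))
  paths$latentStats <- .writeCsv(stats, outDir, "latent_family_stats.csv")
  pca <- pcaProject(Z, 2L)
  paths$pca <- .writeCsv(
    data.frame(family = fam, pc1 = pca$scores[, 1], pc2 = pca$scores[, 2]),
    outDir, "pca_scores.csv")

  target <- config$targetFamily
  kalModel <- stage("kal", {
    asm <- assembleTrainingSet(
      positives = lib[fam == target],
      kinaseNegatives = lib[!isBg & fam != target],
      backgroundPool = lib[isBg],
      backgroundN = config$kal$backgroundN,
      positiveClass = target, seed = seeds[["kal"]])
    trainKal(asm, ntree = config$kal$ntree, folds = config$kal$folds,
             evaluation = "cv", seed = seeds[["kal"]])
  })
  ev <- kalModel@evaluation
  paths$kalMetrics <- .writeCsv(ev$metrics$perClass, outDir,
                                "kal_binary_metrics.csv")
  paths$kalImportance <- .writeCsv(featureImportances(kalModel), outDir,
                                   "kal_feature_importances.csv")
  kalMulti <- NULL
  if (isTRUE(config$kal$multiclass)) {
    kalMulti <- stage("kal_multiclass", {
      kin <- lib[!isBg]
      trainKal(kin, labels = molFamily(kin), positiveClass = target,
               ntree = config$kal$ntree, folds = config$kal$folds,
               evaluation = "cv", seed = seeds[["kal"]])
    })
    paths$kalMultiMetrics <- .writeCsv(
      kalMulti@evaluation$metrics$perClass, outDir,
      "kal_multiclass_metrics.csv")
  }

  Zkin <- Z[!isBg, , drop = FALSE]
  clust <- stage("cluster", {
    if (isTRUE(config$cluster$selectK)) {
      evaluator <- makeRemodelEvaluator(
        lib[!isBg], vae, .remodelConfigFrom(config, seeds[["remodel"]]))
      sel <- selectK(Zkin, config$cluster$candidateKs, evaluator,
                     seed = seeds[["cluster"]])
      paths$selectK <<- .writeCsv(sel$table, outDir, "select_k.csv")
      kmeansFit(Zkin, sel$k, seed = seeds[["cluster"]])
    } else {
      kmeansFit(Zkin, config$cluster$k, seed = seeds[["cluster"]])
    }
  })

  refs <- lib[fam == target]
  gen <- stage("remodel", generateNeighborhood(
    lib[!isBg], vae, kalModel, clust,
    config = .remodelConfigFrom(config, seeds[["remodel"]]), refs = refs))
  paths$generated <- stage("remodel", writeGeneratedCsv(
    gen, file.path(outDir, "generated.csv")))
  paths$ledger <- .writeCsv(gen@ledger, outDir, "generation_ledger.csv")

  report <- stage("report", generationReport(
    gen, refs = refs, kalThreshold = config$report$kalThreshold,
    similarityThreshold = config$report$similarityThreshold))
  paths$report <- file.path(outDir, "generation_report.json")
  jsonlite::write_json(
    report[c("nValid", "nQualifiers", "qualifierPct", "kalMeanQualifiers",
             "kalMax", "meanMaxTanimoto", "maxTanimoto",
             "nHighSimilarity")],
    paths$report, auto_unbox = TRUE, digits = NA, na = "null")
  if (nrow(report$attribution)) {
    paths$attribution <- .writeCsv(report$attribution, outDir,
                                   "qualifier_attribution.csv")
  }

  boRun <- NULL
  if (isTRUE(config$bo$enabled)) {
    boRun <- stage("bo", {
      box <- latentBox(Z)
      cfg <- boConfig(box$lower, box$upper,
                      nInitRandom = config$bo$nInitRandom,
                      maxSteps = config$bo$maxSteps,
                      plateauWindow = config$bo$plateauWindow,
                      plateauTol = config$bo$plateauTol,
                      refitPeriod = config$bo$refitPeriod,
                      eiJitter = config$bo$eiJitter,
                      acqRestarts = config$bo$acqRestarts,
                      seed = seeds[["bo"]])
      pol <- .decodePolicyFrom(config)
      obj <- makeKalObjective(vae, kalModel, pol)
      seedsZ <- NULL
      if (identical(config$bo$mode, "biased")) {
        zt <- encodeLatent(vae, refs)
        seedsZ <- zt[seq_len(min(nrow(zt), config$bo$nSeeded)), ,
                     drop = FALSE]
      }
      runBo(obj, cfg, seeds = seedsZ)
    })
    paths$boHistory <- .writeCsv(boRun@history, outDir, "bo_history.csv")
  }

  manifest <- list(
    package = "kinoforge",
    globalSeed = config$seed,
    stageSeeds = as.list(seeds),
    config = unclass(config),
    counts = list(library = length(lib),
                  kinase = sum(!isBg), background = sum(isBg),
                  generated = length(gen),
                  qualified = report$nQualifiers))
  paths$manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(library = lib, vae = vae, kalModel = kalModel,
                 kalMulti = kalMulti, clusterModel = clust,
                 generated = gen, report = report, bo = boRun,
                 latentStats = stats, pca = pca, seeds = seeds,
                 paths = paths))
}

.decodePolicyFrom <- function(config) {
  decodePolicy(maxAttempts = config$remodel$maxAttempts,
               temperature = config$remodel$temperature,
               minSmilesLength = config$remodel$minSmilesLength)
}

.remodelConfigFrom <- function(config, seed) {
  remodelConfig(s = config$remodel$s, noiseSd = config$remodel$noiseSd,
                noiseMode = config$remodel$noiseMode,
                kalThreshold = config$remodel$kalThreshold,
                tanimotoThreshold = config$remodel$tanimotoThreshold,
                decodePolicy = .decodePolicyFrom(config), seed = seed)
}
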