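#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- MoleculeSet

#' MoleculeSet: a standardized molecule library
#'
#' Container for canonical-SMILES molecules with optional family labels,
#' potency values (nM) and free-text provenance. Construct with
#' \code{\link{MoleculeSet}}; produce standardized sets from raw input with
#' \code{\link{standardizeMolecules}}.
#'
#' @slot smiles character vector of canonical SMILES.
#' @slot family character vector of family labels (NA when unknown).
#' @slot activity numeric potency values in nM (NA when unknown).
#' @slot sourceId character provenance strings.
#'
#' @aliases MoleculeSet-class
#' @export
setClass("MoleculeSet",
  representation(smiles = "character", family = "character",
                 activity = "numeric", sourceId = "character"))

setValidity("MoleculeSet", function(object) {
  n <- length(object@smiles)
  if (length(object@family) != n || length(object@activity) != n ||
      length(object@sourceId) != n) {
    return("slot lengths differ")
  }
  if (anyNA(object@smiles) || any(!nzchar(object@smiles))) {
    return("smiles must be non-empty and non-NA")
  }
  TRUE
})

#' Construct a MoleculeSet
#'
#' @param smiles character vector of SMILES (assumed canonical; use
#'   \code{\link{standardizeMolecules}} for raw input).
#' @param family,activity,sourceId optional per-molecule metadata, recycled
#'   from scalars.
#' @return a \linkS4class{MoleculeSet}.
#' @export
MoleculeSet <- function(smiles, family = NA_character_,
                        activity = NA_real_, sourceId = NA_character_) {
  n <- length(smiles)
  new("MoleculeSet", smiles = as.character(smiles),
      family = as.character(recycleTo(family, n, "family")),
      activity = as.numeric(recycleTo(activity, n, "activity")),
      sourceId = as.character(recycleTo(sourceId, n, "sourceId")))
}

#' @describeIn MoleculeSet number of molecules.
#' @param x a MoleculeSet.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@smiles))

#' @export
setMethod("smiles", "MoleculeSet", function(x) x@smiles)

#' @export
setMethod("molFamily", "MoleculeSet", function(x) x@family)

#' @export
setMethod("activities", "MoleculeSet", function(x) x@activity)

#' @export
setMethod("sourceIds", "MoleculeSet", function(x) x@sourceId)

#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
  new("MoleculeSet", smiles = x@smiles[i], family = x@family[i],
      activity = x@activity[i], sourceId = x@sourceId[i])
})

#' @export
setMethod("c", "MoleculeSet", function(x, ...) {
  rest <- list(...)
  new("MoleculeSet",
      smiles = c(x@smiles, unlist(lapply(rest, smiles))),
      family = c(x@family, unlist(lapply(rest, molFamily))),
      activity = c(x@activity, unlist(lapply(rest, activities))),
      sourceId = c(x@sourceId, unlist(lapply(rest, sourceIds))))
})

#' @export
setMethod("show", "MoleculeSet", function(object) {
  fam <- unique(object@family[!is.na(object@family)])
  cat(sprintf("MoleculeSet with %d molecules", length(object)))
  if (length(fam)) {
    cat(sprintf(" across %d families (%s)", length(fam),
                paste(utils::head(fam, 5), collapse = ", ")))
  }
  cat("\n")
  if (length(object)) {
    cat("  first: ", utils::head(object@smiles, 3), "\n")
  }
})

#' @export
setMethod("as.data.frame", "MoleculeSet", function(x, ...) {
  data.frame(smiles = x@smiles, family = x@family,
             activity_nM = x@activity, source_id = x@sourceId,
             stringsAsFactors = FALSE)
})

# ------------------------------------------------------------- FingerprintSet

#' FingerprintSet: Morgan fingerprints for a set of molecules
#'
#' Circular-substructure hash fingerprints stored as sorted 0-based on-bit
#' indices, parameterized by radius and bit-vector length. Built with
#' \code{\link{morganFingerprints}}.
#'
#' @slot bits list of integer vectors of on-bit indices.
#' @slot radius Morgan radius.
#' @slot nBits folded bit-vector length.
#' @slot smiles the molecules the fingerprints belong to.
#' @aliases FingerprintSet-class
#' @export
setClass("FingerprintSet",
  representation(bits = "list", radius = "integer", nBits = "integer",
                 smiles = "character"))

setValidity("FingerprintSet", function(object) {
  if (length(object@bits) != length(object@smiles)) {
    return("bits and smiles lengths differ")
  }
  ok <- vapply(object@bits, function(b) {
    length(b) == 0L || (min(b) >= 0L && max(b) < object@nBits)
  }, logical(1))
  if (!all(ok)) return("bit indices out of [0, nBits)")
  TRUE
})

#' @export
setMethod("length", "FingerprintSet", function(x) length(x@bits))

#' @export
setMethod("[", "FingerprintSet", function(x, i, j, ..., drop = TRUE) {
  new("FingerprintSet", bits = x@bits[i], radius = x@radius,
      nBits = x@nBits, smiles = x@smiles[i])
})

#' @export
setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d fingerprints (radius %d, %d bits)\n",
              length(object), object@radius, object@nBits))
})

# ------------------------------------------------------------ TokenVocabulary

#' TokenVocabulary: character-level SMILES tokenization scheme
#'
#' Ordered token list with the three special tokens (\code{<pad>},
#' \code{<sos>}, \code{<eos>}) in the first positions, plus the maximum
#' sequence length (in tokens) the models built on it accept. Multi-character
#' organic-subset element symbols (\code{Cl}, \code{Br}), two-digit ring
#' closures (\code{\%nn}) and full bracket atoms are atomic tokens.
#'
#' @slot tokens ordered character vector of tokens (specials first).
#' @slot maxLength maximum token-sequence length.
#' @aliases TokenVocabulary-class
#' @export
setClass("TokenVocabulary",
  representation(tokens = "character", maxLength = "integer"))

setValidity("TokenVocabulary", function(object) {
  if (anyDuplicated(object@tokens)) return("duplicate tokens")
  if (!identical(object@tokens[1:3], c("<pad>", "<sos>", "<eos>"))) {
    return("tokens must start with <pad>, <sos>, <eos>")
  }
  if (object@maxLength < 1L) return("maxLength must be >= 1")
  TRUE
})

#' @export
setMethod("show", "TokenVocabulary", function(object) {
  cat(sprintf("TokenVocabulary: %d tokens, maxLength %d\n",
              length(object@tokens), object@maxLength))
})

# -------------------------------------------------------------------- VaeModel

#' VaeModel: character-level SMILES variational autoencoder
#'
#' A position-factorized feed-forward VAE over tokenized SMILES: a tanh
#' encoder maps the one-hot sequence to a Gaussian posterior in latent
#' space, and a tanh decoder maps a latent point to per-position token
#' distributions. Encoding is deterministic (posterior mean); decoding is
#' stochastic temperature sampling. Train with \code{\link{trainVae}}.
#'
#' @slot vocab the \linkS4class{TokenVocabulary}.
#' @slot latentDim latent dimensionality (196 by default in training).
#' @slot hiddenDim hidden-layer width.
#' @slot params list of weight matrices/bias vectors.
#' @slot trainingLog per-epoch loss trajectory.
#' @slot config training configuration actually used.
#' @slot seed training seed.
#' @aliases VaeModel-class
#' @export
setClass("VaeModel",
  representation(vocab = "TokenVocabulary", latentDim = "integer",
                 hiddenDim = "integer", params = "list",
                 trainingLog = "data.frame", config = "list",
                 seed = "integer"))

#' @export
setMethod("show", "VaeModel", function(object) {
  tl <- object@trainingLog
  cat(sprintf(
    "VaeModel: latent %d, hidden %d, vocab %d tokens, maxLength %d\n",
    object@latentDim, object@hiddenDim, length(object@vocab@tokens),
    object@vocab@maxLength))
  if (nrow(tl)) {
    cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n", nrow(tl),
                tl$loss[1], tl$loss[nrow(tl)]))
  }
})

#' @export
setMethod("latentDim", "VaeModel", function(model) model@latentDim)

# ---------------------------------------------------------------- DecodePolicy

#' DecodePolicy: decode-with-retries protocol parameters
#'
#' The decoder is run up to \code{maxAttempts} times per latent vector; the
#' first draw that parses as a valid molecule and whose canonical SMILES has
#' at least \code{minSmilesLength} characters is kept.
#'
#' @slot maxAttempts maximum decoder draws per vector (default 500).
#' @slot temperature softmax sampling temperature.
#' @slot minSmilesLength minimum canonical-SMILES character length
#'   (default 10; strings shorter than this are discarded).
#' @slot seed optional RNG seed (NA uses the ambient stream).
#' @aliases DecodePolicy-class
#' @export
setClass("DecodePolicy",
  representation(maxAttempts = "integer", temperature = "numeric",
                 minSmilesLength = "integer", seed = "integer"),
  prototype(maxAttempts = 500L, temperature = 1.0,
            minSmilesLength = 10L, seed = NA_integer_))

setValidity("DecodePolicy", function(object) {
  if (object@maxAttempts < 1L) return("maxAttempts must be >= 1")
  if (object@minSmilesLength < 0L) return("minSmilesLength must be >= 0")
  if (object@temperature <= 0) return("temperature must be > 0")
  TRUE
})

#' Construct a DecodePolicy
#' @param maxAttempts,temperature,minSmilesLength,seed see
#'   \linkS4class{DecodePolicy}.
#' @return a \linkS4class{DecodePolicy}.
#' @export
decodePolicy <- function(maxAttempts = 500L, temperature = 1.0,
                         minSmilesLength = 10L, seed = NA_integer_) {
  new("DecodePolicy", maxAttempts = as.integer(maxAttempts),
      temperature = as.numeric(temperature),
      minSmilesLength = as.integer(minSmilesLength),
      seed = as.integer(seed))
}

# ------------------------------------------------------------ TrainingAssembly

#' TrainingAssembly: labelled training set for the KAL classifier
#'
#' Positives are target-family ligands; negatives combine other-family
#' ligands with a seeded uniform subsample of a drug-like background pool.
#' Classes are disjoint by canonical SMILES. Built with
#' \code{\link{assembleTrainingSet}}.
#'
#' @slot molecules the pooled \linkS4class{MoleculeSet}.
#' @slot labels factor of class labels aligned with \code{molecules}.
#' @slot positiveClass label of the positive class.
#' @slot seed subsample seed.
#' @slot log list of assembly diagnostics (overlap removals, pool sizes).
#' @aliases TrainingAssembly-class
#' @export
setClass("TrainingAssembly",
  representation(molecules = "MoleculeSet", labels = "factor",
                 positiveClass = "character", seed = "integer",
                 log = "list"))

setValidity("TrainingAssembly", function(object) {
  if (length(object@molecules) != length(object@labels)) {
    return("labels and molecules lengths differ")
  }
  pos <- smiles(object@molecules)[object@labels == object@positiveClass]
  neg <- smiles(object@molecules)[object@labels != object@positiveClass]
  if (length(intersect(pos, neg))) {
    return("positive and negative classes share molecules")
  }
  TRUE
})

#' @export
setMethod("length", "TrainingAssembly", function(x) length(x@molecules))

#' @export
setMethod("show", "TrainingAssembly", function(object) {
  tab <- table(object@labels)
  cat(sprintf("TrainingAssembly: %d molecules (positive class '%s')\n",
              length(object), object@positiveClass))
  print(tab)
})

# --------------------------------------------------------------------- KalModel

#' KalModel: random-forest family-association likelihood scorer
#'
#' A random forest over the fixed 20-descriptor panel whose positive-class
#' vote fraction is the Kinase Association Likelihood (KAL): the probability
#' that a molecule lies in the chemical space of the target family's
#' ligands. Supports a binary (target vs. rest) and a multiclass mode.
#' Train with \code{\link{trainKal}}.
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot featureNames descriptor ordering used in training (and scoring).
#' @slot mode "binary" or "multiclass".
#' @slot positiveClass positive class label (binary mode).
#' @slot classLevels all class labels.
#' @slot evaluation list with cross-validated (or resubstitution) metrics.
#' @slot seed training seed.
#' @aliases KalModel-class
#' @export
setClass("KalModel",
  representation(forest = "ANY", featureNames = "character",
                 mode = "character", positiveClass = "character",
                 classLevels = "character", evaluation = "list",
                 seed = "integer"))

#' @export
setMethod("show", "KalModel", function(object) {
  cat(sprintf("KalModel (%s): %d trees, %d descriptors, classes: %s\n",
              object@mode, object@forest$ntree,
              length(object@featureNames),
              paste(object@classLevels, collapse = ", ")))
  ev <- object@evaluation
  if (!is.null(ev$auc)) {
    cat(sprintf("  %s ROC-AUC %.3f\n", ev$method %||% "", ev$auc))
  }
})

# ------------------------------------------------------------------ GpSurrogate

#' GpSurrogate: Gaussian-process surrogate with a Matern 5/2 kernel
#'
#' Zero-trend GP regression on (latent vector, score) pairs with an
#' isotropic Matern 5/2 covariance, fitted by maximizing the log marginal
#' likelihood over length-scale, signal variance and noise variance.
#' The Cholesky factorization is cached for prediction.
#'
#' @slot X training inputs (rows are latent vectors).
#' @slot y training targets.
#' @slot logParams log(lengthscale), log(signal sd), log(noise sd).
#' @slot yMean constant mean subtracted from targets.
#' @slot L lower Cholesky factor of the training covariance.
#' @slot alpha cached solve of the centered targets.
#' @aliases GpSurrogate-class
#' @export
setClass("GpSurrogate",
  representation(X = "matrix", y = "numeric", logParams = "numeric",
                 yMean = "numeric", L = "matrix", alpha = "numeric"))

#' @export
setMethod("show", "GpSurrogate", function(object) {
  p <- exp(object@logParams)
  cat(sprintf(
    "GpSurrogate: %d points in %d-d; lengthscale %.3g, signal %.3g, noise %.3g\n",
    nrow(object@X), ncol(object@X), p[1], p[2], p[3]))
})

# ---------------------------------------------------------------------- BoConfig

#' BoConfig: Bayesian-optimization protocol parameters
#'
#' Mirrors the search protocol: a bounded latent box, random and/or seeded
#' initialization, Expected Improvement maximized by multi-start L-BFGS-B,
#' periodic marginal-likelihood refits, and a step-cap plus KAL-plateau
#' stopping rule (default: stop after 1500 acquisition steps or when the
#' best score improves by less than 0.001 over 100 consecutive steps).
#'
#' @slot lower,upper per-dimension search bounds.
#' @slot nInitRandom number of uniform initial probes.
#' @slot maxSteps acquisition-step cap (default 1500).
#' @slot plateauWindow,plateauTol plateau stopping rule.
#' @slot refitPeriod hyperparameter refit period in steps (default 100).
#' @slot eiJitter EI exploration jitter xi.
#' @slot acqRestarts L-BFGS-B restarts per acquisition.
#' @slot gpCap largest history size fitted exactly; beyond it the GP is
#'   refit on the best point plus the most recent \code{gpCap - 1}.
#' @slot seed run seed.
#' @aliases BoConfig-class
#' @export
setClass("BoConfig",
  representation(lower = "numeric", upper = "numeric",
                 nInitRandom = "integer", maxSteps = "integer",
                 plateauWindow = "integer", plateauTol = "numeric",
                 refitPeriod = "integer", eiJitter = "numeric",
                 acqRestarts = "integer", gpCap = "integer",
                 seed = "integer"))

setValidity("BoConfig", function(object) {
  if (length(object@lower) != length(object@upper)) {
    return("lower/upper lengths differ")
  }
  if (any(!is.finite(object@lower)) || any(!is.finite(object@upper))) {
    return("bounds must be finite")
  }
  if (any(object@lower >= object@upper)) return("need lower < upper")
  if (object@maxSteps < 1L) return("maxSteps must be >= 1")
  TRUE
})

#' Construct a BoConfig
#' @param lower,upper numeric per-dimension search bounds.
#' @param nInitRandom,maxSteps,plateauWindow,plateauTol,refitPeriod,eiJitter,acqRestarts,gpCap,seed
#'   see \linkS4class{BoConfig}.
#' @return a \linkS4class{BoConfig}.
#' @export
boConfig <- function(lower, upper, nInitRandom = 10L, maxSteps = 1500L,
                     plateauWindow = 100L, plateauTol = 0.001,
                     refitPeriod = 100L, eiJitter = 0.01,
                     acqRestarts = 10L, gpCap = 300L, seed = NA_integer_) {
  new("BoConfig", lower = as.numeric(lower), upper = as.numeric(upper),
      nInitRandom = as.integer(nInitRandom), maxSteps = as.integer(maxSteps),
      plateauWindow = as.integer(plateauWindow),
      plateauTol = as.numeric(plateauTol),
      refitPeriod = as.integer(refitPeriod),
      eiJitter = as.numeric(eiJitter),
      acqRestarts = as.integer(acqRestarts), gpCap = as.integer(gpCap),
      seed = as.integer(seed))
}

# -------------------------------------------------------------------------- BoRun

#' BoRun: record of one Bayesian-optimization run
#'
#' @slot history data.frame with one row per evaluation (phase, step,
#'   score, best-so-far).
#' @slot Z matrix of evaluated latent vectors (rows align with history).
#' @slot stopReason "max_steps" or "plateau".
#' @slot decoded per-step decode ledger for acquisition vectors (when an
#'   embedding model was supplied).
#' @slot config the \linkS4class{BoConfig} used.
#' @aliases BoRun-class
#' @export
setClass("BoRun",
  representation(history = "data.frame", Z = "matrix",
                 stopReason = "character", decoded = "data.frame",
                 config = "BoConfig"))

#' @export
setMethod("show", "BoRun", function(object) {
  h <- object@history
  cat(sprintf("BoRun: %d evaluations (%d init), best %.4f, stopped: %s\n",
              nrow(h), sum(h$phase == "init"), max(h$best), object@stopReason))
})

# -------------------------------------------------------------------- ClusterModel

#' ClusterModel: seeded K-means partition of a latent cloud
#'
#' @slot centroids k x d matrix of cluster centroids.
#' @slot assignments integer cluster index per input point.
#' @slot inertia total within-cluster sum of squares.
#' @slot k number of clusters.
#' @slot seed seed used for k-means++ initialization.
#' @aliases ClusterModel-class
#' @export
setClass("ClusterModel",
  representation(centroids = "matrix", assignments = "integer",
                 inertia = "numeric", k = "integer", seed = "integer"))

#' @export
setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d in %d-d, inertia %.3f, sizes: %s\n",
              object@k, ncol(object@centroids), object@inertia,
              paste(tabulate(object@assignments, object@k), collapse = "/")))
})

# ------------------------------------------------------------------ RemodelConfig

#' RemodelConfig: centroid-directed local remodeling parameters
#'
#' Governs x* = x + s (c - x) + eps: the scaling factor s in [0, 1]
#' (default 0.8), the isotropic noise standard deviation (default 5.0, in
#' raw latent units; "relative" mode scales it by the per-dimension spread
#' of the reference embedding), the decode policy, and the KAL/similarity
#' qualification thresholds.
#'
#' @slot s scaling factor in [0, 1]; 0 keeps the original encoding, 1 jumps
#'   to the centroid.
#' @slot noiseSd isotropic noise sd (0 disables noise).
#' @slot noiseMode "absolute" (raw latent units) or "relative"
#'   (multiples of the per-dimension sd of the encoded reference library).
#' @slot kalThreshold KAL qualification cutoff (default 0.7; generated
#'   molecules scoring above it are flagged potential target-family-like).
#' @slot tanimotoThreshold high-similarity cutoff (default 0.75).
#' @slot decodePolicy the \linkS4class{DecodePolicy} used when decoding.
#' @slot seed run seed.
#' @aliases RemodelConfig-class
#' @export
setClass("RemodelConfig",
  representation(s = "numeric", noiseSd = "numeric", noiseMode = "character",
                 kalThreshold = "numeric", tanimotoThreshold = "numeric",
                 decodePolicy = "DecodePolicy", seed = "integer"),
  prototype(s = 0.8, noiseSd = 5.0, noiseMode = "absolute",
            kalThreshold = 0.7, tanimotoThreshold = 0.75, seed = NA_integer_))

setValidity("RemodelConfig", function(object) {
  if (object@s < 0 || object@s > 1) return("s must be in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!object@noiseMode %in% c("absolute", "relative")) {
    return("noiseMode must be 'absolute' or 'relative'")
  }
  TRUE
})

#' Construct a RemodelConfig
#' @param s,noiseSd,noiseMode,kalThreshold,tanimotoThreshold,decodePolicy,seed
#'   see \linkS4class{RemodelConfig}.
#' @return a \linkS4class{RemodelConfig}.
#' @export
remodelConfig <- function(s = 0.8, noiseSd = 5.0, noiseMode = "absolute",
                          kalThreshold = 0.7, tanimotoThreshold = 0.75,
                          decodePolicy = kinoforge::decodePolicy(),
                          seed = NA_integer_) {
  new("RemodelConfig", s = as.numeric(s), noiseSd = as.numeric(noiseSd),
      noiseMode = noiseMode, kalThreshold = as.numeric(kalThreshold),
      tanimotoThreshold = as.numeric(tanimotoThreshold),
      decodePolicy = decodePolicy, seed = as.integer(seed))
}

# ------------------------------------------------------------------- GeneratedSet

#' GeneratedSet: decoded molecules with provenance and scores
#'
#' One row per unique generated molecule (duplicates are collapsed with a
#' multiplicity count), carrying the origin family and source molecule, the
#' decode attempt count, the KAL score and qualification flag, similarity
#' to the reference set and drug-likeness properties. A per-input fate
#' ledger accounts for every input molecule in exactly one of
#' generated / decode_failed / length_filtered / descriptor_failed.
#'
#' @slot results data.frame of generated molecules.
#' @slot ledger data.frame with one row per input molecule and its fate.
#' @slot params list of generation parameters.
#' @aliases GeneratedSet-class
#' @export
setClass("GeneratedSet",
  representation(results = "data.frame", ledger = "data.frame",
                 params = "list"))

#' @export
setMethod("length", "GeneratedSet", function(x) nrow(x@results))

#' @export
setMethod("show", "GeneratedSet", function(object) {
  cat(sprintf(
    "GeneratedSet: %d unique molecules from %d inputs (%d qualified)\n",
    nrow(object@results), nrow(object@ledger),
    if (nrow(object@results)) sum(object@results$qualified) else 0L))
  if (nrow(object@ledger)) {
    print(table(object@ledger$fate))
  }
})

#' @export
setMethod("as.data.frame", "GeneratedSet", function(x, ...) x@results)
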