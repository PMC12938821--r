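#' @include vae.R kal.R
NULL

#' Seeded K-means partition of latent vectors
#'
#' Lloyd iteration with seeded k-means++ initialization, run until
#' assignment convergence or the iteration cap. Every point ends assigned
#' to its nearest centroid and the within-cluster inertia is
#' non-increasing across iterations.
#'
#' @param Z numeric matrix of latent vectors.
#' @param k number of clusters (must not exceed the number of points).
#' @param seed seed for the k-means++ initialization.
#' @param maxIter Lloyd iteration cap.
#' @return a \linkS4class{ClusterModel}.
#' @export
kmeansFit <- function(Z, k, seed = 1L, maxIter = 100L) {
  Z <- as.matrix(Z)
  if (k > nrow(Z)) {
    stop(sprintf("k (%d) exceeds number of points (%d)", k, nrow(Z)))
  }
  withSeed(seed, {
    centers <- .kmeansPlusPlus(Z, k)
    fit <- suppressWarnings(
      stats::kmeans(Z, centers = centers, iter.max = maxIter,
                    algorithm = "Lloyd"))
    new("ClusterModel", centroids = unname(fit$centers),
        assignments = as.integer(fit$cluster),
        inertia = fit$tot.withinss, k = as.integer(k),
        seed = as.integer(seed))
  })
}

# k-means++ seeding: first centroid uniform, then proportional to squared
# distance to the nearest chosen centroid.
.kmeansPlusPlus <- function(Z, k) {
  n <- nrow(Z)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(Z, 2L, Z[idx[1], ])^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(Z, 2L, Z[idx[j + 1L], ])^2))
  }
  Z[idx, , drop = FALSE]
}

# nearest-centroid assignment for new points
nearestCentroid <- function(Z, centroids) {
  d2 <- outer(rowSums(Z^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(Z, centroids)
  max.col(-d2, ties.method = "first")
}

#' Centroid-directed latent remodeling
#'
#' The local remodeling step x* = x + s (c - x) + eps: each latent point is
#' moved the fraction \code{s} of the way toward its centroid and perturbed
#' by isotropic Gaussian noise of standard deviation \code{noiseSd}
#' (\code{eps = 0} when \code{noiseSd = 0}). With s = 0 and no noise the
#' original encoding is returned; with s = 1 the centroid itself. Noise
#' draws consume the ambient RNG stream.
#'
#' @param x latent vector or matrix (rows remodeled independently).
#' @param centroid centroid vector, or matrix with one row per row of
#'   \code{x}.
#' @param s scaling factor in [0, 1].
#' @param noiseSd isotropic noise sd (scalar, or vector of per-dimension
#'   sds).
#' @return remodeled vector/matrix of the same shape as \code{x}.
#' @export
remodel <- function(x, centroid, s = 0.8, noiseSd = 5.0) {
  stopifnot(s >= 0, s <= 1, all(noiseSd >= 0))
  vec <- is.null(dim(x))
  x <- rbind(x)
  centroid <- rbind(centroid)
  if (nrow(centroid) == 1L && nrow(x) > 1L) {
    centroid <- centroid[rep(1L, nrow(x)), , drop = FALSE]
  }
  if (!all(dim(x) == dim(centroid))) {
    stop("x and centroid dimensions do not match")
  }
  out <- x + s * (centroid - x)
  if (any(noiseSd > 0)) {
    eps <- matrix(stats::rnorm(length(out)), nrow(out), ncol(out))
    eps <- sweep(eps, 2L, recycleTo(noiseSd, ncol(out), "noiseSd"), "*")
    out <- out + eps
  }
  if (vec) out[1, ] else out
}

#' Choose the cluster count by a remodeling trial
#'
#' For each candidate k, runs a small remodeling trial through the supplied
#' evaluator and scores the valid-molecule yield and the scaffold diversity
#' of the outputs. The chosen k maximizes validity first, with diversity as
#' the tie-break; remaining ties go to the smallest k. Evaluator failures
#' are recorded and the k excluded.
#'
#' @param Z latent matrix to cluster.
#' @param candidateKs integer candidates (the protocol sweeps 2 to 5).
#' @param evaluator function(k, clusterModel) returning a list with
#'   \code{validYield} and \code{diversity}; see
#'   \code{\link{makeRemodelEvaluator}}.
#' @param seed clustering seed.
#' @return list with \code{k} (chosen) and \code{table} (one row per
#'   candidate).
#' @export
selectK <- function(Z, candidateKs = 2:5, evaluator, seed = 1L) {
  stopifnot(length(candidateKs) > 0L)
  rows <- lapply(candidateKs, function(k) {
    cm <- kmeansFit(Z, k, seed = spawnSeed(seed, paste0("k", k)))
    res <- tryCatch(evaluator(k, cm), error = function(e) {
      list(validYield = NA_real_, diversity = NA_real_,
           error = conditionMessage(e))
    })
    data.frame(k = k, validYield = res$validYield,
               diversity = res$diversity,
               error = res$error %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$validYield))
  if (!length(ok)) stop("evaluator failed for every candidate k")
  ord <- ok[order(-tab$validYield[ok], -tab$diversity[ok], tab$k[ok])]
  list(k = tab$k[ord[1]], table = tab)
}

#' Default remodeling-trial evaluator for selectK
#'
#' Builds the evaluator used by \code{\link{selectK}}: encode the trial
#' inputs, remodel toward their centroids under the config, decode with
#' retries, and score validity (valid fraction of inputs) and diversity
#' (mean pairwise Tanimoto distance of the valid outputs).
#'
#' @param inputs trial molecules.
#' @param vae embedding model.
#' @param config a \linkS4class{RemodelConfig}.
#' @return function(k, clusterModel) for \code{\link{selectK}}.
#' @export
makeRemodelEvaluator <- function(inputs, vae, config = remodelConfig()) {
  Z <- encodeLatent(vae, inputs)
  baseSeed <- if (is.na(config@seed)) 1L else config@seed
  function(k, clusterModel) {
    assign <- nearestCentroid(Z, clusterModel@centroids)
    withSeed(spawnSeed(baseSeed, paste0("trial", k)), {
      noiseSd <- .resolveNoiseSd(config, Z)
      Zs <- remodel(Z, clusterModel@centroids[assign, , drop = FALSE],
                    s = config@s, noiseSd = noiseSd)
      decs <- .decodeBatch(vae, Zs, config@decodePolicy)
      smi <- vapply(decs, `[[`, "", "smiles")
      valid <- !is.na(smi)
      diversity <- if (sum(valid) >= 2L) {
        fp <- morganFingerprints(unique(smi[valid]))
        if (length(fp) < 2L) 0 else {
          tm <- tanimoto(fp, fp)
          mean(1 - tm[upper.tri(tm)])
        }
      } else 0
      list(validYield = mean(valid), diversity = diversity)
    })
  }
}

# noise sd in raw units, resolving "relative" mode against the reference
# embedding's per-dimension spread
.resolveNoiseSd <- function(config, Z) {
  if (config@noiseMode == "relative") {
    config@noiseSd * apply(Z, 2L, stats::sd)
  } else {
    config@noiseSd
  }
}

#' Cluster-guided local neighborhood generation
#'
#' The local remodeling pipeline: each input molecule is encoded, moved
#' toward its cluster centroid (x* = x + s (c - x) + eps), decoded under
#' the retry policy, length-filtered and KAL-scored. Outputs carry origin
#' family, source molecule, attempt counts, KAL score and the
#' qualification flag (KAL above the config threshold marks a potential
#' target-family-like ligand). Duplicated decodes are collapsed with a
#' multiplicity count. A per-input fate ledger accounts for every input in
#' exactly one of generated / decode_failed / length_filtered /
#' descriptor_failed.
#'
#' @param inputs \linkS4class{MoleculeSet} of source molecules.
#' @param vae embedding model.
#' @param kalModel trained \linkS4class{KalModel}.
#' @param clusterModel \linkS4class{ClusterModel} over the same latent
#'   space.
#' @param config a \linkS4class{RemodelConfig}.
#' @param refs optional reference molecules for Tanimoto similarity
#'   columns.
#' @return a \linkS4class{GeneratedSet}.
#' @export
generateNeighborhood <- function(inputs, vae, kalModel, clusterModel,
                                 config = remodelConfig(), refs = NULL) {
  stopifnot(is(inputs, "MoleculeSet"), is(config, "RemodelConfig"))
  Z <- encodeLatent(vae, inputs)
  assign <- nearestCentroid(Z, clusterModel@centroids)
  withSeed(config@seed, {
    noiseSd <- .resolveNoiseSd(config, Z)
    Zs <- remodel(Z, clusterModel@centroids[assign, , drop = FALSE],
                  s = config@s, noiseSd = noiseSd)
    n <- length(inputs)
    decs <- .decodeBatch(vae, Zs, config@decodePolicy)
    fate <- vapply(decs, `[[`, "", "status")
    outSmi <- vapply(decs, `[[`, "", "smiles")
    attempts <- vapply(decs, function(d) as.integer(d$attempts),
                       integer(1))
    gen <- which(fate == "ok")
    kal <- rep(NA_real_, n)
    if (length(gen)) {
      kal[gen] <- suppressWarnings(kalScore(kalModel, outSmi[gen]))
      descFail <- gen[is.na(kal[gen])]
      fate[descFail] <- "descriptor_failed"
      gen <- gen[!is.na(kal[gen])]
    }
    fate[fate == "ok"] <- "generated"

    results <- data.frame(smiles = character(0), origin_family = character(0),
                          source_smiles = character(0), kal = numeric(0),
                          attempts = integer(0), multiplicity = integer(0),
                          qualified = logical(0), stringsAsFactors = FALSE)
    if (length(gen)) {
      df <- data.frame(smiles = outSmi[gen],
                       origin_family = molFamily(inputs)[gen],
                       source_smiles = smiles(inputs)[gen],
                       kal = kal[gen], attempts = attempts[gen],
                       stringsAsFactors = FALSE)
      mult <- table(df$smiles)
      df <- df[!duplicated(df$smiles), , drop = FALSE]
      df$multiplicity <- as.integer(mult[df$smiles])
      df$qualified <- df$kal > config@kalThreshold
      desc <- computeDescriptors(df$smiles)
      df$qed <- desc$qed; df$logp <- desc$logp; df$sas <- desc$sas
      if (!is.null(refs)) {
        sim <- maxSimilarityToReference(df$smiles, refs)
        df$max_tanimoto <- sim$score
        df$nearest_ref <- sim$nearest
      } else {
        df$max_tanimoto <- NA_real_
        df$nearest_ref <- NA_character_
      }
      rownames(df) <- NULL
      results <- df
    }
    ledger <- data.frame(smiles = smiles(inputs),
                         family = molFamily(inputs),
                         cluster = assign, fate = fate,
                         attempts = attempts, stringsAsFactors = FALSE)
    new("GeneratedSet", results = results, ledger = ledger,
        params = list(s = config@s, noiseSd = config@noiseSd,
                      noiseMode = config@noiseMode,
                      kalThreshold = config@kalThreshold,
                      tanimotoThreshold = config@tanimotoThreshold,
                      k = clusterModel@k, seed = config@seed))
  })
}

#' Write a GeneratedSet as CSV
#' @param gen a \linkS4class{GeneratedSet}.
#' @param path output path.
#' @export
writeGeneratedCsv <- function(gen, path) {
  cols <- c("smiles", "origin_family", "source_smiles", "kal",
            "max_tanimoto", "nearest_ref", "qed", "logp", "sas",
            "attempts", "multiplicity", "qualified")
  df <- gen@results
  utils::write.csv(df[intersect(cols, names(df))], path, row.names = FALSE)
  invisible(path)
}
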