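#' @include chemstore.R
NULL

#' PCA projection of a latent cloud
#'
#' Mean-centered orthogonal projection onto the leading principal
#' components, ordered by explained variance.
#'
#' @param Z numeric matrix (rows are latent vectors).
#' @param nComponents number of components (default 2).
#' @return list with \code{scores}, \code{rotation},
#'   \code{explainedVariance} (proportions over all dimensions) and
#'   \code{center}.
#' @export
pcaProject <- function(Z, nComponents = 2L) {
  Z <- as.matrix(Z)
  if (nComponents > ncol(Z)) {
    stop(sprintf("nComponents (%d) exceeds dimension (%d)",
                 nComponents, ncol(Z)))
  }
  if (nrow(Z) < nComponents) stop("need at least nComponents points")
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
       rotation = pc$rotation[, seq_len(nComponents), drop = FALSE],
       explainedVariance = ev,
       center = pc$center)
}

#' Kernel-density map of a 2-d projection
#'
#' Gaussian kernel density on a regular grid spanning the data range plus
#' a margin, with per-axis bandwidths from Scott's rule
#' (sd * n^(-1/6) for two dimensions). Grid-cell masses integrate to ~1.
#'
#' @param P n x 2 matrix of projected points.
#' @param gridN grid resolution per axis (default 200).
#' @param margin fractional range expansion (default 0.05).
#' @param bandwidth optional per-axis kernel sd override.
#' @return list with \code{x}, \code{y}, \code{z} (density matrix) and
#'   \code{bandwidth}.
#' @export
kdeDensity <- function(P, gridN = 200L, margin = 0.05, bandwidth = NULL) {
  P <- as.matrix(P)
  stopifnot(ncol(P) == 2L)
  if (nrow(P) < 2L) stop("need at least 2 points")
  sds <- apply(P, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (zero-variance) projection; jitter the data")
  }
  h <- bandwidth %||% (sds * nrow(P)^(-1 / 6))
  span <- apply(P, 2L, range)
  ext <- (span[2, ] - span[1, ]) * margin
  lims <- c(span[1, 1] - ext[1], span[2, 1] + ext[1],
            span[1, 2] - ext[2], span[2, 2] + ext[2])
  # MASS::kde2d's h is 4x the Gaussian kernel sd
  kd <- MASS::kde2d(P[, 1], P[, 2], h = 4 * h, n = gridN, lims = lims)
  list(x = kd$x, y = kd$y, z = kd$z, bandwidth = h)
}

#' Per-family latent statistics
#'
#' For each family: the global minimum and maximum over all latent entries
#' (range), and the extrema of the per-dimension means and standard
#' deviations, aggregated across all latent dimensions. Families with a
#' single vector report zero standard deviations.
#'
#' @param Z latent matrix.
#' @param families family label per row.
#' @return data.frame with columns \code{family}, \code{minRange},
#'   \code{maxRange}, \code{minAverage}, \code{maxAverage},
#'   \code{minStandDev}, \code{maxStandDev}.
#' @export
familyLatentStats <- function(Z, families) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(families))
  fams <- unique(families[!is.na(families)])
  rows <- lapply(fams, function(f) {
    Zi <- Z[which(families == f), , drop = FALSE]
    mu <- colMeans(Zi)
    sds <- if (nrow(Zi) > 1L) apply(Zi, 2L, stats::sd) else {
      rep(0, ncol(Zi))
    }
    data.frame(family = f, minRange = min(Zi), maxRange = max(Zi),
               minAverage = min(mu), maxAverage = max(mu),
               minStandDev = min(sds), maxStandDev = max(sds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# fixed-rule histogram helpers for the report
.intHist <- function(x) {
  if (!length(x)) return(data.frame(bin = integer(0), count = integer(0)))
  tab <- table(factor(round(x), levels = seq(0, max(round(x)))))
  data.frame(bin = as.integer(names(tab)), count = as.integer(tab))
}

.contHist <- function(x, nBins = 20L) {
  if (!length(x)) {
    return(data.frame(lower = numeric(0), upper = numeric(0),
                      count = integer(0)))
  }
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  br <- seq(rng[1], rng[2], length.out = nBins + 1L)
  ct <- hist(x, breaks = br, plot = FALSE)$counts
  data.frame(lower = br[-length(br)], upper = br[-1], count = ct)
}

#' Generation report
#'
#' Summary computations over a generated set: the number of valid unique
#' molecules, the qualifier count and percentage (KAL above
#' \code{kalThreshold}; rounded half-up to two decimals), KAL mean and
#' maximum among qualifiers and the overall maximum, the mean and maximum
#' of the per-molecule maximum Tanimoto similarity to the reference set
#' with the high-similarity count (above \code{similarityThreshold}),
#' property histograms (integer bins for aromatic rings, 20 equal-width
#' bins for QED/logP/SAS/LabuteASA/molecular weight) and, among
#' qualifiers, the per-origin-family attribution fractions (summing to 1).
#' An empty generated set yields a defined all-zero report.
#'
#' @param gen a \linkS4class{GeneratedSet} (or its results data.frame).
#' @param refs optional reference molecules for similarity (recomputed if
#'   the set lacks similarity columns).
#' @param kalThreshold qualifier cutoff (0.5 is the exploration baseline;
#'   0.7 flags potential target-family-like ligands).
#' @param similarityThreshold high-similarity cutoff (default 0.75).
#' @return object of class \code{generationReport}.
#' @export
generationReport <- function(gen, refs = NULL, kalThreshold = 0.5,
                             similarityThreshold = 0.75) {
  df <- if (is(gen, "GeneratedSet")) gen@results else as.data.frame(gen)
  empty <- list(
    nValid = 0L, nQualifiers = 0L, qualifierPct = 0,
    kalMeanQualifiers = NA_real_, kalMaxQualifiers = NA_real_,
    kalMax = NA_real_, meanMaxTanimoto = NA_real_, maxTanimoto = NA_real_,
    nHighSimilarity = 0L, propertyMeans = c(qed = NA_real_,
                                            logp = NA_real_,
                                            sas = NA_real_),
    histograms = list(), attribution = data.frame(
      family = character(0), fraction = numeric(0)),
    kalThreshold = kalThreshold,
    similarityThreshold = similarityThreshold)
  if (!nrow(df)) return(structure(empty, class = "generationReport"))

  if (!is.null(refs) &&
      (!"max_tanimoto" %in% names(df) || anyNA(df$max_tanimoto))) {
    sim <- maxSimilarityToReference(df$smiles, refs)
    df$max_tanimoto <- sim$score
    df$nearest_ref <- sim$nearest
  }
  desc <- computeDescriptors(df$smiles)
  qual <- df$kal > kalThreshold
  nValid <- nrow(df)
  rep <- list(
    nValid = nValid,
    nQualifiers = sum(qual),
    qualifierPct = roundHalfUp(100 * sum(qual) / nValid, 2L),
    kalMeanQualifiers = if (any(qual)) mean(df$kal[qual]) else NA_real_,
    kalMaxQualifiers = if (any(qual)) max(df$kal[qual]) else NA_real_,
    kalMax = max(df$kal),
    meanMaxTanimoto = if ("max_tanimoto" %in% names(df)) {
      mean(df$max_tanimoto)
    } else NA_real_,
    maxTanimoto = if ("max_tanimoto" %in% names(df)) {
      max(df$max_tanimoto)
    } else NA_real_,
    nHighSimilarity = if ("max_tanimoto" %in% names(df)) {
      sum(df$max_tanimoto > similarityThreshold)
    } else 0L,
    propertyMeans = c(qed = mean(desc$qed), logp = mean(desc$logp),
                      sas = mean(desc$sas),
                      molecular_weight = mean(desc$molecular_weight),
                      labute_asa = mean(desc$labute_asa)),
    histograms = list(
      aromatic_rings = .intHist(desc$aromatic_rings),
      qed = .contHist(desc$qed), logp = .contHist(desc$logp),
      sas = .contHist(desc$sas),
      molecular_weight = .contHist(desc$molecular_weight),
      labute_asa = .contHist(desc$labute_asa)),
    attribution = if (any(qual) && "origin_family" %in% names(df)) {
      tab <- table(df$origin_family[qual])
      data.frame(family = names(tab),
                 fraction = as.numeric(tab) / sum(tab),
                 stringsAsFactors = FALSE)
    } else data.frame(family = character(0), fraction = numeric(0)),
    kalThreshold = kalThreshold,
    similarityThreshold = similarityThreshold)
  structure(rep, class = "generationReport")
}

#' @export
print.generationReport <- function(x, ...) {
  cat(sprintf("Generation report: %d valid molecules\n", x$nValid))
  cat(sprintf("  KAL > %.2f: %d (%.2f%%); mean among qualifiers %.4f; max %.4f\n",
              x$kalThreshold, x$nQualifiers, x$qualifierPct,
              x$kalMeanQualifiers, x$kalMax))
  if (!is.na(x$meanMaxTanimoto)) {
    cat(sprintf("  Tanimoto to refs: mean max %.4f, max %.4f, > %.2f: %d\n",
                x$meanMaxTanimoto, x$maxTanimoto, x$similarityThreshold,
                x$nHighSimilarity))
  }
  if (!all(is.na(x$propertyMeans))) {
    cat("  property means:",
        paste(sprintf("%s %.3f", names(x$propertyMeans),
                      x$propertyMeans), collapse = ", "), "\n")
  }
  if (nrow(x$attribution)) {
    cat("  qualifier attribution:",
        paste(sprintf("%s %.1f%%", x$attribution$family,
                      100 * x$attribution$fraction), collapse = ", "),
        "\n")
  }
  invisible(x)
}
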