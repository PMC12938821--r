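test_that("PCA projection is centered, ordered and reconstructs the data", {
  set.seed(3)
  Z <- matrix(rnorm(200), ncol = 4) %*% diag(c(4, 2, 1, 0.5))
  p <- pcaProject(Z, 2L)
  expect_true(!is.unsorted(rev(p$explainedVariance)))
  centerProj <- (colMeans(Z) - p$center) %*% p$rotation
  expect_equal(as.numeric(centerProj), c(0, 0), tolerance = 1e-10)

  # data stretched along a known axis: first component parallel up to sign
  axis <- c(1, 2, 0) / sqrt(5)
  Zs <- outer(rnorm(100, sd = 5), axis) + matrix(rnorm(300, sd = 0.05),
                                                 ncol = 3)
  ps <- pcaProject(Zs, 2L)
  expect_gt(abs(sum(ps$rotation[, 1] * axis)), 0.999)

  # full-rank projection then back-projection reproduces centered data
  full <- pcaProject(Z, 4L)
  back <- full$scores %*% t(full$rotation)
  expect_equal(back, sweep(Z, 2L, colMeans(Z)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaProject(Z, 9L), "exceeds")
})

test_that("kernel density maps integrate to one and respond to bandwidth", {
  set.seed(11)
  P <- cbind(rnorm(300), rnorm(300, sd = 2))
  kd <- kdeDensity(P, gridN = 120L)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  expect_equal(sum(kd$z) * dx * dy, 1, tolerance = 0.02)

  # tight cloud: density argmax lands within a kernel bandwidth (or one
  # grid cell, whichever is coarser) of the sample mean
  Pt <- cbind(rnorm(400, 3, 0.05), rnorm(400, -2, 0.05))
  kt <- kdeDensity(Pt, gridN = 80L)
  peak <- which(kt$z == max(kt$z), arr.ind = TRUE)[1, ]
  tolx <- max(2 * kt$bandwidth[1], diff(kt$x[1:2]))
  toly <- max(2 * kt$bandwidth[2], diff(kt$y[1:2]))
  expect_lt(abs(kt$x[peak[1]] - mean(Pt[, 1])), tolx)
  expect_lt(abs(kt$y[peak[2]] - mean(Pt[, 2])), toly)

  kw <- kdeDensity(P, gridN = 120L, bandwidth = 2 * kd$bandwidth)
  expect_lt(max(kw$z), max(kd$z))
  expect_error(kdeDensity(cbind(rep(1, 10), rnorm(10))), "jitter")
})

test_that("family latent statistics match hand computation", {
  Z <- rbind(c(1, 2, 3, 4),
             c(0, 1, 5, -1),
             c(2, 0, 1, 1))
  fam <- c("A", "A", "B")
  st <- familyLatentStats(Z, fam)
  a <- st[st$family == "A", ]
  expect_equal(a$minRange, -1)
  expect_equal(a$maxRange, 5)
  expect_equal(a$minAverage, min(colMeans(Z[1:2, ])))
  expect_equal(a$maxAverage, 4)
  expect_equal(a$minStandDev, min(apply(Z[1:2, ], 2, sd)))
  expect_equal(a$maxStandDev, max(apply(Z[1:2, ], 2, sd)))
  b <- st[st$family == "B", ]
  expect_equal(b$minStandDev, 0)
  expect_equal(b$maxStandDev, 0)
  expect_identical(names(st), c("family", "minRange", "maxRange",
                                "minAverage", "maxAverage",
                                "minStandDev", "maxStandDev"))
})

test_that("distinct scaffold families separate in the embedded projection", {
  lib <- tinyLibrary()
  fam <- molFamily(lib)
  keep <- fam %in% c("SRC", "background")
  Z <- encodeLatent(tinyVae(), lib[keep])
  p <- pcaProject(Z, 2L)$scores
  grp <- fam[keep]
  cSrc <- colMeans(p[grp == "SRC", , drop = FALSE])
  cBg <- colMeans(p[grp == "background", , drop = FALSE])
  spread <- mean(c(apply(p[grp == "SRC", , drop = FALSE], 2, sd),
                   apply(p[grp == "background", , drop = FALSE], 2, sd)))
  expect_gt(sqrt(sum((cSrc - cBg)^2)), spread)
})

test_that("the generation report reproduces the printed qualifier arithmetic", {
  # 153 qualifiers among 492 valid -> 31.10%
  df <- data.frame(
    smiles = rep(c("OCCc1ccccc1", "CCOc1ccccc1", "CCN(C)c1ccccc1",
                   "CCCCOc1ccccc1"), length.out = 492),
    origin_family = rep(c("LCK", "EGFR", "ABL1"), length.out = 492),
    kal = c(rep(0.8, 153), rep(0.2, 339)),
    stringsAsFactors = FALSE)
  rep1 <- generationReport(df, kalThreshold = 0.5)
  expect_equal(rep1$nValid, 492L)
  expect_equal(rep1$nQualifiers, 153L)
  expect_equal(rep1$qualifierPct, 31.10)
})

test_that("report summaries equal a brute-force recomputation", {
  set.seed(14)
  smi <- sample(smiles(tinyLibrary()), 20)
  df <- data.frame(smiles = smi,
                   origin_family = sample(c("LCK", "ABL1"), 20,
                                          replace = TRUE),
                   kal = runif(20), stringsAsFactors = FALSE)
  refs <- tinyLibrary()[seq_len(8)]
  rp <- generationReport(df, refs = refs, kalThreshold = 0.5)

  qual <- df$kal > 0.5
  expect_equal(rp$nQualifiers, sum(qual))
  expect_equal(rp$qualifierPct,
               floor(100 * 100 * sum(qual) / 20 + 0.5) / 100)
  expect_equal(rp$kalMeanQualifiers, mean(df$kal[qual]))
  expect_equal(rp$kalMax, max(df$kal))
  sims <- maxSimilarityToReference(df$smiles, refs)$score
  expect_equal(rp$meanMaxTanimoto, mean(sims))
  expect_equal(rp$maxTanimoto, max(sims))
  expect_equal(rp$nHighSimilarity, sum(sims > 0.75))
  desc <- computeDescriptors(df$smiles)
  expect_equal(unname(rp$propertyMeans["qed"]), mean(desc$qed))
  expect_equal(unname(rp$propertyMeans["logp"]), mean(desc$logp))
  expect_equal(unname(rp$propertyMeans["sas"]), mean(desc$sas))
  # conservation laws
  expect_equal(sum(rp$histograms$aromatic_rings$count), 20L)
  expect_equal(sum(rp$histograms$qed$count), 20L)
  if (nrow(rp$attribution)) {
    expect_equal(sum(rp$attribution$fraction), 1)
  }
  att <- rp$attribution
  want <- table(df$origin_family[qual])
  expect_equal(att$fraction[match(names(want), att$family)],
               as.numeric(want) / sum(want))
})

test_that("an empty generated set yields a defined zero report", {
  emptyGen <- new("GeneratedSet",
                  results = data.frame(), ledger = data.frame(),
                  params = list())
  rp <- generationReport(emptyGen, kalThreshold = 0.5)
  expect_equal(rp$nValid, 0L)
  expect_equal(rp$nQualifiers, 0L)
  expect_equal(rp$qualifierPct, 0)
  expect_equal(nrow(rp$attribution), 0L)
})
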