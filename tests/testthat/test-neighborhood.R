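test_that("k-means: k = 1 is the mean, separated blobs are recovered exactly", {
  set.seed(4)
  Z <- matrix(rnorm(60), ncol = 3)
  cm1 <- kmeansFit(Z, 1L, seed = 2L)
  expect_equal(as.numeric(cm1@centroids), colMeans(Z), tolerance = 1e-12)

  fx <- generateLatentFixture(150, means = rbind(c(0, 0), c(25, 0),
                                                 c(0, 25)),
                              sds = 1, seed = 9L)
  cm <- kmeansFit(fx$Z, 3L, seed = 5L)
  tab <- table(fx$labels, cm@assignments)
  # adjusted agreement 1: one-to-one mapping between labels and clusters
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  # every point sits with its nearest centroid, and the fitted inertia is
  # no worse than the inertia of the k-means++ initialization
  near <- kinoforge:::nearestCentroid(fx$Z, cm@centroids)
  expect_identical(near, cm@assignments)
  init <- kinoforge:::withSeed(5L, kinoforge:::.kmeansPlusPlus(fx$Z, 3L))
  a0 <- kinoforge:::nearestCentroid(fx$Z, init)
  inertia0 <- sum((fx$Z - init[a0, ])^2)
  expect_lte(cm@inertia, inertia0 + 1e-9)

  expect_error(kmeansFit(Z, 100L), "exceeds")
})

test_that("selectK follows validity-first ranking with smallest-k ties", {
  Z <- matrix(rnorm(60), ncol = 2)
  stub <- function(k, cm) {
    list(validYield = c(`2` = 0.5, `3` = 0.9, `4` = 0.6,
                        `5` = 0.4)[[as.character(k)]],
         diversity = 0.5)
  }
  sel <- selectK(Z, 2:5, stub, seed = 1L)
  expect_identical(sel$k, 3L)
  expect_equal(nrow(sel$table), 4L)

  tied <- function(k, cm) list(validYield = 0.7, diversity = 0.5)
  expect_identical(selectK(Z, 2:5, tied, seed = 1L)$k, 2L)

  flaky <- function(k, cm) {
    if (k == 2) stop("boom") else list(validYield = k / 10,
                                       diversity = 0.1)
  }
  sel3 <- selectK(Z, 2:4, flaky, seed = 1L)
  expect_identical(sel3$k, 4L)
  expect_true(is.na(sel3$table$validYield[sel3$table$k == 2]))
})

test_that("remodeling obeys the interpolation identities", {
  x <- c(0, 0); cc <- c(10, 10)
  expect_equal(remodel(x, cc, s = 0, noiseSd = 0), x)
  expect_equal(remodel(x, cc, s = 1, noiseSd = 0), cc)
  expect_equal(remodel(x, cc, s = 0.8, noiseSd = 0), c(8, 8))
  expect_error(remodel(c(0, 0), c(1, 2, 3), s = 0.5, noiseSd = 0),
               "dimensions")
  # contraction identity ||x* - c|| = (1 - s) ||x - c||, exactly
  set.seed(6)
  for (i in 1:25) {
    d <- sample(2:8, 1)
    x <- rnorm(d); cc <- rnorm(d); s <- runif(1)
    xs <- remodel(x, cc, s = s, noiseSd = 0)
    expect_equal(sqrt(sum((xs - cc)^2)), (1 - s) * sqrt(sum((x - cc)^2)),
                 tolerance = 1e-12)
  }
})

test_that("neighborhood generation conserves every input in one fate", {
  inputs <- tinyLibrary()[seq_len(12)]
  cm <- new("ClusterModel", centroids = matrix(0, 2, 3),
            assignments = rep(1L, 12), inertia = 0, k = 2L, seed = 1L)
  fakeKal <- new("FakeKal", scores = c(0.72, 0.3))

  # stub decoder that never produces a valid string -> empty set, all
  # inputs accounted as decode_failed
  dead <- new("FakeEmbedder", dim = 3L, table = list(), draws = "xx")
  gen0 <- generateNeighborhood(inputs, dead, fakeKal, cm,
                               remodelConfig(noiseSd = 0,
                                             decodePolicy = decodePolicy(
                                               maxAttempts = 5L),
                                             seed = 1L))
  expect_equal(length(gen0), 0L)
  expect_equal(nrow(gen0@ledger), 12L)
  expect_true(all(gen0@ledger$fate == "decode_failed"))

  # stub decoder always valid: qualification follows the 0.7 threshold
  ok <- new("FakeEmbedder", dim = 3L, table = list(),
            draws = "c1ccccc1CCOCC")
  gen1 <- generateNeighborhood(inputs, ok,
                               new("FakeKal", scores = 0.72), cm,
                               remodelConfig(noiseSd = 0,
                                             decodePolicy = decodePolicy(
                                               maxAttempts = 5L),
                                             seed = 1L))
  expect_equal(sum(gen1@ledger$fate == "generated"), 12L)
  expect_equal(nrow(gen1@results), 1L)  # duplicates collapsed
  expect_equal(gen1@results$multiplicity, 12L)
  expect_true(gen1@results$qualified)
  gen1b <- generateNeighborhood(inputs, ok,
                                new("FakeKal", scores = 0.70), cm,
                                remodelConfig(noiseSd = 0,
                                              decodePolicy = decodePolicy(
                                                maxAttempts = 5L),
                                              seed = 1L))
  expect_false(gen1b@results$qualified)  # strict > 0.7

  # real pipeline: conservation across fates
  gen <- generateNeighborhood(
    tinyLibrary()[molFamily(tinyLibrary()) != "background"][1:25],
    tinyVae(), tinyKal(), tinyClusters(),
    remodelConfig(decodePolicy = decodePolicy(maxAttempts = 60L,
                                              temperature = 0.8),
                  seed = 17L),
    refs = tinyLibrary()[molFamily(tinyLibrary()) == "SRC"])
  expect_equal(nrow(gen@ledger), 25L)
  expect_true(all(gen@ledger$fate %in%
                    c("generated", "decode_failed", "length_filtered",
                      "descriptor_failed")))
  expect_equal(sum(gen@results$multiplicity),
               sum(gen@ledger$fate == "generated"))
})

test_that("identical seeds reproduce the generated set exactly", {
  inputs <- tinyLibrary()[molFamily(tinyLibrary()) != "background"][1:10]
  cfg <- remodelConfig(decodePolicy = decodePolicy(maxAttempts = 40L,
                                                   temperature = 0.8),
                       seed = 23L)
  g1 <- generateNeighborhood(inputs, tinyVae(), tinyKal(),
                             tinyClusters(), cfg)
  g2 <- generateNeighborhood(inputs, tinyVae(), tinyKal(),
                             tinyClusters(), cfg)
  expect_identical(g1@results, g2@results)
  expect_identical(g1@ledger, g2@ledger)
})
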