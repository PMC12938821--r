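# unique placeholder SMILES strings for count-level assembly tests (the
# assembly only keys on string identity)
fakeSet <- function(prefix, n) {
  MoleculeSet(paste0(prefix, seq_len(n)))
}

test_that("training assembly reproduces the reference pool arithmetic", {
  # 1502 positives + ~9000 kinase negatives + 14530 background subsample
  asm <- assembleTrainingSet(fakeSet("P", 1502), fakeSet("K", 9000),
                             fakeSet("B", 20000), backgroundN = 14530,
                             seed = 1L)
  expect_equal(length(asm), 25032L)
  expect_equal(sum(asm@labels == "negative"), 23530L)
  expect_equal(sum(asm@labels == "positive"), 1502L)
})

test_that("assembly subsampling is seeded and classes stay disjoint", {
  a1 <- assembleTrainingSet(fakeSet("P", 10), fakeSet("K", 20),
                            fakeSet("B", 100), backgroundN = 30, seed = 4L)
  a2 <- assembleTrainingSet(fakeSet("P", 10), fakeSet("K", 20),
                            fakeSet("B", 100), backgroundN = 30, seed = 4L)
  expect_identical(smiles(a1@molecules), smiles(a2@molecules))

  # overlapping pools: duplicates leave the negatives, with a logged count
  pos <- MoleculeSet(c("P1", "P2", "P3"))
  kin <- MoleculeSet(c("P1", "K1", "K2"))
  bg <- MoleculeSet(c("P2", "B1", "B2", "B3"))
  a3 <- assembleTrainingSet(pos, kin, bg, backgroundN = 3, seed = 1L)
  negSmi <- smiles(a3@molecules)[a3@labels == "negative"]
  expect_false(any(c("P1", "P2", "P3") %in% negSmi))
  expect_equal(a3@log$overlapRemoved, 2L)
  expect_error(
    assembleTrainingSet(pos, kin, bg, backgroundN = 50, seed = 1L),
    "smaller")
})

test_that("the designed ring signal is learnable with ring features top-ranked", {
  kal <- tinyKal()
  expect_gte(kal@evaluation$auc, 0.95)
  fi <- featureImportances(kal)
  expect_equal(nrow(fi), 20L)
  expect_equal(sum(fi$importance), 1, tolerance = 1e-9)
  expect_true(all(fi$importance >= 0))
  expect_true(!is.unsorted(rev(fi$importance)))
  ringFeatures <- c("aromatic_rings", "aromatic_carbocycles",
                    "aromatic_heterocycles", "ring_count",
                    "aromatic_atom_fraction")
  expect_true(any(head(fi$feature, 5) %in% ringFeatures))
})

test_that("KAL scores are probabilities and overfit positives score high", {
  kal <- tinyKal()
  sc <- kalScore(kal, smiles(tinyLibrary())[seq(1, 180, by = 12)])
  expect_true(all(sc >= 0 & sc <= 1))
  # resubstitution: a training positive in the fitted forest scores >= 0.5
  lib <- tinyLibrary()
  fam <- molFamily(lib)
  pos <- smiles(lib)[fam == "SRC"][1]
  expect_gte(kalScore(kal, pos), 0.5)
  # scoring is deterministic
  expect_identical(sc, kalScore(kal,
                                smiles(tinyLibrary())[seq(1, 180, by = 12)]))
  expect_error(trainKal(lib[fam == "SRC"],
                        labels = rep("SRC", sum(fam == "SRC"))),
               "single class")
})

test_that("classification metrics equal a brute-force confusion computation", {
  bruteMetrics <- function(truth, pred) {
    lev <- sort(union(unique(truth), unique(pred)))
    per <- lapply(lev, function(cl) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      c(p = p, r = r, f = f, s = sum(truth == cl))
    })
    m <- do.call(rbind, per)
    list(acc = mean(truth == pred), p = m[, "p"], r = m[, "r"],
         f = m[, "f"], s = m[, "s"])
  }
  set.seed(33)
  for (rep in 1:5) {
    truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
    pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
    got <- classificationMetrics(truth, pred)
    want <- bruteMetrics(truth, pred)
    expect_equal(got$accuracy, want$acc)
    expect_equal(got$perClass$precision, unname(want$p))
    expect_equal(got$perClass$recall, unname(want$r))
    expect_equal(got$perClass$f1, unname(want$f))
    expect_equal(got$perClass$support, unname(as.integer(want$s)))
    expect_equal(unname(got$macro["f1"]), mean(want$f))
    expect_equal(unname(got$weighted["f1"]),
                 sum(want$f * want$s / sum(want$s)))
  }
  # all-correct predictions
  perfect <- classificationMetrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$perClass$f1, c(1, 1))
  # equal supports make macro and weighted coincide
  eq <- classificationMetrics(rep(c("a", "b"), each = 10),
                              rep(c("a", "b"), times = 10))
  expect_equal(eq$macro, eq$weighted)
  expect_error(classificationMetrics(character(0), character(0)), "empty")
  expect_warning(classificationMetrics(c("a", "a"), c("a", "z")),
                 "zero support")
})

test_that("ROC-AUC equals the pairwise rank-comparison oracle", {
  bruteAuc <- function(lab, sc) {
    pos <- sc[lab]; neg <- sc[!lab]
    tot <- 0
    for (p in pos) for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
    tot / (length(pos) * length(neg))
  }
  expect_equal(rocAuc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.2, 0.1)),
               1)
  expect_equal(rocAuc(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4)), 0.5)
  lab6 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  sc6 <- c(0.9, 0.9, 0.7, 0.4, 0.3, 0.1)
  expect_equal(rocAuc(lab6, sc6), bruteAuc(lab6, sc6))
  set.seed(21)
  for (rep in 1:5) {
    lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (all(lab) || !any(lab)) next
    sc <- round(runif(40), 1)  # force ties
    expect_equal(rocAuc(lab, sc), bruteAuc(lab, sc))
  }
  expect_error(rocAuc(rep(TRUE, 5), runif(5)), "both classes")
})

test_that("ROC-AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  lab <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  sc <- runif(100) + lab * 0.3
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, sc))))
  expect_equal(rocAuc(lab, sc), ref)
})

test_that("binary target-vs-rest beats multiclass for overlapping families", {
  # families that share scaffold features: two quinazoline-like cores with
  # overlapping substituent pools, so the multiclass task dilutes signal
  spec <- librarySpec(
    families = list(
      SRC = list(core = "{R}Nc1ncnc2ccccc12", n = 40L),
      LCK = list(core = "{R}Nc1ccnc2ccccc12", n = 40L),
      ABL1 = list(core = "{R}Nc1ncnc2ccccc12", n = 40L),
      EGFR = list(core = "{R}Nc1ccnc2ccccc12", n = 40L)),
    background = list(templates = c("{R}CC(=O)OCC", "{R}CCNCC(C)O",
                                    "{R}CCOCCOC"), n = 80L),
    substituents = c("", "C", "CC", "CCC", "OC", "OCC", "CCO", "CN(C)C",
                     "CC(C)", "NC(C)"),
    seed = 13L)
  lib <- generateToyLibrary(spec)
  fam <- molFamily(lib)
  asm <- assembleTrainingSet(lib[fam == "SRC"],
                             lib[fam != "SRC" & fam != "background"],
                             lib[fam == "background"],
                             positiveClass = "SRC", seed = 3L)
  bin <- trainKal(asm, ntree = 300L, seed = 6L)
  kin <- lib[fam != "background"]
  multi <- trainKal(kin, labels = molFamily(kin), positiveClass = "SRC",
                    ntree = 300L, seed = 6L)
  f1of <- function(model) {
    pc <- model@evaluation$metrics$perClass
    pc$f1[pc$class == "SRC"]
  }
  expect_gt(f1of(bin), f1of(multi))
})
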