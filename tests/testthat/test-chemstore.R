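test_that("standardization keeps the largest organic fragment and is idempotent", {
  expect_identical(standardizeMolecule("CCO.[Na+].[Cl-]"), "CCO")
  # hand-drawn check: acetate salt keeps the acetate parent
  expect_identical(standardizeMolecule("CC(=O)[O-].[Na+]"),
                   standardizeMolecule("CC(=O)O"))
  smi <- head(smiles(tinyLibrary()), 25)
  again <- vapply(smi, standardizeMolecule, "", USE.NAMES = FALSE)
  expect_identical(again, smi)
})

test_that("standardization errors carry the offending input", {
  expect_error(standardizeMolecule("C1CC"), "C1CC")
  expect_error(standardizeMolecule("[Na+].[Cl-]"), "organic parent")
  expect_error(standardizeMolecule(""), "empty")
})

test_that("vectorized standardization reports rejects instead of failing", {
  res <- standardizeMolecules(c("CCO", "C1CC", "[Na+].[Cl-]", "c1ccccc1"),
                              family = c("a", "b", "c", "d"))
  expect_identical(smiles(res$molecules), c("CCO", "c1ccccc1"))
  expect_identical(molFamily(res$molecules), c("a", "d"))
  expect_identical(res$rejected$reason, c("parse_error", "empty_parent"))
})

test_that("descriptors match structure-forced values and are deterministic", {
  d <- computeDescriptors(c("c1ccccc1", "CCO", "c1ccc2ccccc2c1"))
  # benzene
  expect_equal(d$aromatic_rings[1], 1)
  expect_equal(d$aromatic_carbocycles[1], 1)
  expect_equal(d$aromatic_heterocycles[1], 0)
  expect_equal(d$hbd[1], 0)
  expect_equal(d$rotatable_bonds[1], 0)
  # ethanol
  expect_equal(d$ring_count[2], 0)
  expect_equal(d$hbd[2], 1)
  expect_equal(d$sp3_fraction[2], 1.0)
  # naphthalene
  expect_equal(d$aromatic_rings[3], 2)
  expect_equal(d$aromatic_carbocycles[3], 2)
  expect_equal(d$aromatic_atom_fraction[3], 1.0)

  expect_identical(names(d), descriptorNames())
  expect_identical(d, computeDescriptors(c("c1ccccc1", "CCO",
                                           "c1ccc2ccccc2c1")))
  # ranges
  lib <- computeDescriptors(tinyLibrary())
  expect_true(all(lib$qed >= 0 & lib$qed <= 1))
  expect_true(all(lib$sp3_fraction >= 0 & lib$sp3_fraction <= 1))
  expect_true(all(lib$aromatic_atom_fraction >= 0 &
                    lib$aromatic_atom_fraction <= 1))
  counts <- c("aromatic_rings", "ring_count", "hbd", "hba",
              "rotatable_bonds", "stereocenters", "amide_bonds",
              "bridgehead_atoms")
  expect_true(all(as.matrix(lib[counts]) >= 0))
  expect_true(all(as.matrix(lib[counts]) == round(as.matrix(lib[counts]))))
})

test_that("library filters reject by rule with conservation", {
  # five molecules, two known violations: a >700 Da chain and a silane
  five <- MoleculeSet(c(
    "c1ccccc1",                                   # fine
    paste0(strrep("C", 52)),                      # MW ~731 > 700
    "C[Si](C)(C)C",                               # element whitelist
    "CCO",                                        # fine
    "c1ccc2ncnc(N)c2c1"))                         # fine
  res <- applyLibraryFilters(five)
  expect_equal(length(res$retained), 3L)
  expect_equal(res$report$rejected[res$report$rule == "mw"], 1L)
  expect_equal(res$report$rejected[res$report$rule == "element"], 1L)
  expect_equal(sum(res$report$rejected) + length(res$retained),
               length(five))

  res2 <- applyLibraryFilters(tinyLibrary())
  expect_equal(sum(res2$report$rejected) + length(res2$retained),
               length(tinyLibrary()))
})

test_that("tanimoto obeys the set formula, symmetry and range", {
  # |A ∩ B| = 2, |A| = 4, |B| = 3 -> 2/5
  a <- new("FingerprintSet", bits = list(c(0L, 1L, 2L, 3L)),
           radius = 2L, nBits = 16L, smiles = "a")
  b <- new("FingerprintSet", bits = list(c(0L, 1L, 9L)),
           radius = 2L, nBits = 16L, smiles = "b")
  expect_equal(tanimoto(a, b), 0.4)
  d <- new("FingerprintSet", bits = list(c(8L, 9L)), radius = 2L,
           nBits = 16L, smiles = "d")
  expect_equal(tanimoto(a, d), 0)

  fp <- morganFingerprints(head(smiles(tinyLibrary()), 12))
  m <- tanimoto(fp, fp)
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(diag(m)), rep(1, length(fp)))

  fp512 <- morganFingerprints("CCO", nBits = 512L)
  expect_error(tanimoto(fp, fp512), "parameters differ")
})

test_that("max similarity to reference matches a brute-force loop", {
  refs <- tinyLibrary()[seq_len(10)]
  q <- smiles(tinyLibrary())[41:45]
  res <- maxSimilarityToReference(q, refs)
  fq <- morganFingerprints(q)
  fr <- morganFingerprints(refs)
  for (i in seq_along(q)) {
    vals <- vapply(seq_len(length(fr)), function(j) {
      tanimoto(fq[i], fr[j])
    }, numeric(1))
    expect_equal(res$score[i], max(vals))
    expect_identical(res$nearest[i], smiles(refs)[which.max(vals)])
  }
  # query present in refs scores 1 with itself as nearest
  self <- maxSimilarityToReference(smiles(refs)[3], refs)
  expect_equal(self$score, 1)
  expect_identical(self$nearest, smiles(refs)[3])
  expect_error(maxSimilarityToReference("CCO", character(0)), "empty")
})

test_that("smi and csv readers round-trip", {
  tmp <- tempfile(fileext = ".smi")
  writeSmiles(c("CCO", "c1ccccc1"), tmp, names = c("ethanol", NA))
  back <- readSmiles(tmp)
  expect_identical(back$smiles, c("CCO", "c1ccccc1"))
  expect_identical(back$name[1], "ethanol")

  tmp2 <- tempfile(fileext = ".csv")
  writeMoleculeCsv(tinyLibrary()[1:5], tmp2)
  back2 <- readMoleculeCsv(tmp2)
  expect_identical(smiles(back2), smiles(tinyLibrary()[1:5]))
  expect_identical(molFamily(back2), molFamily(tinyLibrary()[1:5]))

  tmp3 <- tempfile(fileext = ".csv")
  writeDescriptorCsv(computeDescriptors(c("CCO", "c1ccccc1")), tmp3)
  hdr <- names(utils::read.csv(tmp3))
  expect_identical(hdr, c("smiles", descriptorNames()))
})
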