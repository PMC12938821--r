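# Shared fixtures, built once per test session and memoized. Everything is
# generated in code (no stored data); sizes are kept small so the whole
# suite runs in minutes on one CPU.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# synthetic multi-family library (4 kinase-like families + background)
tinyLibrary <- function() {
  fixture("lib", function() {
    generateToyLibrary(defaultLibrarySpec(seed = 7L, familyN = 25L,
                                          backgroundN = 90L))
  })
}

# small overfit autoencoder on the library corpus
tinyVae <- function() {
  fixture("vae", function() {
    trainVae(unique(smiles(tinyLibrary())), latentDim = 10L,
             hiddenDim = 96L, epochs = 300L, lr = 3e-3,
             klWeightMax = 0.05, seed = 3L)
  })
}

# binary KAL model (SRC vs rest) with cross-validated evaluation
tinyKal <- function() {
  fixture("kal", function() {
    lib <- tinyLibrary()
    fam <- molFamily(lib)
    asm <- assembleTrainingSet(lib[fam == "SRC"],
                               lib[fam != "SRC" & fam != "background"],
                               lib[fam == "background"],
                               positiveClass = "SRC", seed = 2L)
    trainKal(asm, ntree = 300L, seed = 4L)
  })
}

# cluster model over the kinase-family embeddings
tinyClusters <- function() {
  fixture("clusters", function() {
    lib <- tinyLibrary()
    kin <- lib[molFamily(lib) != "background"]
    kmeansFit(encodeLatent(tinyVae(), kin), 3L, seed = 2L)
  })
}

# a lookup-table embedding fake satisfying the pluggable contract:
# encodeLatent returns fixed vectors per molecule, decodeDraws replays a
# configurable draw schedule regardless of z
setClass("FakeEmbedder", representation(dim = "integer", table = "list",
                                        draws = "character"))
setMethod("latentDim", "FakeEmbedder", function(model) model@dim)
setMethod("encodeLatent", "FakeEmbedder", function(model, x, ...) {
  if (is(x, "MoleculeSet")) x <- smiles(x)
  do.call(rbind, lapply(x, function(s) {
    model@table[[s]] %||% rep(0, model@dim)
  }))
})
setMethod("decodeDraws", "FakeEmbedder", function(model, z, n, ...) {
  rep_len(model@draws, n)
})

# a fixed-score stand-in for a KAL model (scores cycle over `scores`)
setClass("FakeKal", representation(scores = "numeric"))
setMethod("kalScore", "FakeKal", function(model, x, ...) {
  if (is(x, "MoleculeSet")) x <- smiles(x)
  rep_len(model@scores, length(x))
})

`%||%` <- kinoforge:::`%||%`
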