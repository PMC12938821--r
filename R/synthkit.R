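#' @include chemstore.R
NULL

#' Specification for a synthetic multi-family molecule library
#'
#' Defines a toy library that emulates the structure of a kinase-ligand
#' corpus: several "families" built on fused aromatic scaffold cores
#' (quinazoline-like, pyrrolopyrimidine-like and related chemotypes, 2-3
#' aromatic rings before substitution) contrasted with a low-ring,
#' mostly acyclic drug-like background. Cores are SMILES templates with a
#' single \code{{R}} attachment point; substituents are SMILES prefixes
#' with their attachment atom last, so substitution is plain string
#' templating with near-100\% validity.
#'
#' @param families named list; each element is
#'   \code{list(core = <template>, n = <size>)}.
#' @param background list with \code{templates} and \code{n}.
#' @param substituents character pool of substituent prefixes (may include
#'   "" for the unsubstituted core).
#' @param arylSubstituents branch-safe substituent pool used inside aryl
#'   linkers (first atom must accept an extra bond).
#' @param seed generation seed.
#' @return object of class \code{librarySpec}.
#' @export
librarySpec <- function(families, background, substituents,
                        arylSubstituents = c("C", "CC", "OC", "CN(C)C"),
                        seed = 1L) {
  stopifnot(length(families) > 0L,
            all(vapply(families, function(f) f$n >= 0, logical(1))),
            background$n >= 0)
  structure(list(families = families, background = background,
                 substituents = substituents,
                 arylSubstituents = arylSubstituents,
                 seed = as.integer(seed)),
            class = "librarySpec")
}

#' Default synthetic kinase-like library specification
#'
#' Four ligand families named after kinase families whose chemotypes the
#' cores echo -- SRC (4-anilinoquinazoline-like, 3 aromatic rings), LCK
#' (pyrrolopyrimidine-like), ABL1 (biaryl aminopyrimidine-like), EGFR
#' (quinazoline ether-like) -- of 60 molecules each, against a 240-molecule
#' acyclic/low-ring background. The families carry at least two more
#' aromatic rings than the background on average, so family-vs-background
#' signal is learnable by descriptor-based classifiers; all molecules are
#' entirely synthetic constructs for pipeline testing, not curated ligands.
#'
#' @param seed generation seed.
#' @param familyN,backgroundN per-family and background sizes.
#' @return a \code{\link{librarySpec}}.
#' @export
defaultLibrarySpec <- function(seed = 1L, familyN = 60L,
                               backgroundN = 240L) {
  librarySpec(
    families = list(
      SRC = list(core = "{R}Nc1ncnc2ccccc12", n = familyN,
                 extra = "c1ccc({R})cc1"),
      LCK = list(core = "{R}Nc1ncnc2[nH]ccc12", n = familyN,
                 extra = "c1ccc({R})cc1"),
      ABL1 = list(core = "{R}Nc1nccc(-c2cccnc2)n1", n = familyN,
                  extra = NULL),
      EGFR = list(core = "{R}Oc1ccc2ncnc(Nc3ccccc3)c2c1", n = familyN,
                  extra = NULL)),
    background = list(
      templates = c("{R}CC(=O)OCC", "{R}CCOC(C)=O", "{R}CC(C)CO",
                    "{R}CCNCC(C)O", "{R}CCN(C)CCO", "{R}CC(O)CNC(C)=O",
                    "{R}CCC(=O)NCC", "{R}CCOCCOC"),
      n = backgroundN),
    substituents = c("", "C", "CC", "CCC", "CC(C)", "CCO", "OC", "OCC",
                     "CN(C)C", "NC(C)", "FC(F)(F)", "ClCC", "CCCO",
                     "CC(C)C", "CCN(C)"),
    seed = seed)
}

# instantiate one template: substituent prefix replaces {R}
.fillTemplate <- function(template, sub) {
  sub("{R}", sub, template, fixed = TRUE)
}

#' Generate a labelled synthetic molecule library
#'
#' Deterministic (per seed) generation of a multi-family library from a
#' \code{\link{librarySpec}}: for each family, substituents are sampled
#' with replacement and attached to the family's core template; background
#' molecules are built the same way from the background templates. Every
#' output is passed through \code{\link{standardizeMolecules}} and must
#' standardize cleanly -- an invalid core or substituent in the spec raises
#' an error naming the offending fragment. Kinase-family molecules get a
#' log-normal synthetic potency (nM); the background gets none.
#'
#' @param spec a \code{\link{librarySpec}}.
#' @return a standardized \linkS4class{MoleculeSet} with family labels
#'   (background labelled "background").
#' @export
generateToyLibrary <- function(spec = defaultLibrarySpec()) {
  stopifnot(inherits(spec, "librarySpec"))
  withSeed(spec$seed, {
    raw <- character(0); fam <- character(0)
    for (fname in names(spec$families)) {
      f <- spec$families[[fname]]
      if (f$n == 0L) next
      subs <- sample(spec$substituents, f$n, replace = TRUE)
      smi <- vapply(subs, function(s) .fillTemplate(f$core, s), "",
                    USE.NAMES = FALSE)
      # optionally swap a fraction of substituents for an aryl linker to
      # widen the family's ring-count distribution; the linker takes its
      # own branch-safe substituent
      if (!is.null(f$extra)) {
        wrap <- stats::runif(f$n) < 0.3
        if (any(wrap)) {
          asub <- sample(spec$arylSubstituents, sum(wrap), replace = TRUE)
          smi[wrap] <- vapply(seq_along(asub), function(j) {
            .fillTemplate(f$core, .fillTemplate(f$extra, asub[j]))
          }, "")
        }
      }
      raw <- c(raw, smi); fam <- c(fam, rep(fname, f$n))
    }
    if (spec$background$n > 0L) {
      tpl <- sample(spec$background$templates, spec$background$n,
                    replace = TRUE)
      subs <- sample(setdiff(spec$substituents, ""), spec$background$n,
                     replace = TRUE)
      raw <- c(raw, mapply(.fillTemplate, tpl, subs, USE.NAMES = FALSE))
      fam <- c(fam, rep("background", spec$background$n))
    }
    act <- ifelse(fam == "background", NA_real_,
                  stats::rlnorm(length(raw), meanlog = log(50),
                                sdlog = 0.8))
    std <- standardizeMolecules(raw, family = fam, activity = act,
                                sourceId = "synthetic")
    if (nrow(std$rejected)) {
      stop(sprintf("library spec produced invalid molecules, e.g. '%s'",
                   std$rejected$input[1]))
    }
    std$molecules
  })
}

#' Draw a Gaussian-mixture latent fixture
#'
#' Seeded draws from a finite Gaussian mixture in latent space, with
#' component labels recorded; used to exercise clustering and optimizer
#' code against a known partition.
#'
#' @param n number of draws.
#' @param means k x d matrix of component means.
#' @param sds per-component (or shared scalar) standard deviation.
#' @param weights mixture weights (default equal); must sum to 1.
#' @param seed draw seed.
#' @return list with \code{Z} (n x d matrix) and \code{labels} (component
#'   index per row).
#' @export
generateLatentFixture <- function(n, means, sds = 1, weights = NULL,
                                  seed = 1L) {
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  weights <- weights %||% rep(1 / k, k)
  stopifnot(length(weights) == k, abs(sum(weights) - 1) < 1e-8, d >= 1L)
  sds <- recycleTo(sds, k, "sds")
  withSeed(seed, {
    labels <- sample.int(k, n, replace = TRUE, prob = weights)
    Z <- means[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d), n, d) * sds[labels]
    list(Z = unname(Z), labels = labels)
  })
}
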