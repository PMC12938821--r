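#' @include AllClasses.R
NULL

#' Names of the 20-descriptor panel, in canonical order
#'
#' The fixed descriptor ordering shared between descriptor matrices and the
#' KAL classifier: aromatic features (aromatic rings / carbocycles /
#' heterocycles), topological complexity (ring count, aliphatic
#' carbocycles / heterocycles, bridgehead atoms), physicochemical
#' properties (molecular weight in Da, logP, QED, SAS, Labute ASA in
#' squared Angstroms, Hall-Kier alpha) and pharmacophoric elements (HBD,
#' HBA, rotatable bonds, sp3 carbon fraction, stereocenters including
#' unassigned ones, amide bonds, aromatic-atom fraction).
#'
#' @return character vector of 20 descriptor names.
#' @export
descriptorNames <- function() {
  c("aromatic_rings", "aromatic_carbocycles", "aromatic_heterocycles",
    "ring_count", "aliphatic_carbocycles", "aliphatic_heterocycles",
    "bridgehead_atoms", "molecular_weight", "logp", "qed", "sas",
    "labute_asa", "hall_kier_alpha", "hbd", "hba", "rotatable_bonds",
    "sp3_fraction", "stereocenters", "amide_bonds",
    "aromatic_atom_fraction")
}

#' Standardize a single SMILES string
#'
#' Keeps the largest organic fragment (heavy-atom count, ties broken by
#' molecular weight), normalizes the tautomer to the toolkit's canonical
#' form, preserves stereo descriptors and emits canonical SMILES.
#' Standardization is idempotent: re-standardizing the output returns it
#' unchanged.
#'
#' @param rawSmiles a single SMILES string.
#' @return the canonical SMILES of the standardized parent molecule.
#' @seealso \code{\link{standardizeMolecules}} for vectorized input with an
#'   error report instead of hard failures.
#' @examples \dontrun{standardizeMolecule("CCO.[Na+].[Cl-]")  # "CCO"}
#' @export
standardizeMolecule <- function(rawSmiles) {
  stopifnot(is.character(rawSmiles), length(rawSmiles) == 1L)
  if (!nzchar(rawSmiles)) stop("empty SMILES input")
  res <- rdkitStandardize(rawSmiles)[[1]]
  if (res$status == "parse_error") {
    stop(sprintf("unparsable SMILES: '%s'", rawSmiles))
  }
  if (res$status == "empty_parent") {
    stop(sprintf("no organic parent fragment in: '%s'", rawSmiles))
  }
  if (res$status != "ok") {
    stop(sprintf("standardization failed for '%s' (%s)",
                 rawSmiles, res$status))
  }
  res$smiles
}

#' Standardize a molecule library
#'
#' Vectorized standardization with per-record error capture: unparsable
#' SMILES and salt-only records are collected in a rejection report instead
#' of aborting the batch.
#'
#' @param x character vector of raw SMILES, a data.frame with a
#'   \code{smiles} column (optional \code{family}, \code{activity_nM},
#'   \code{source_id}), or a \linkS4class{MoleculeSet}.
#' @param family,activity,sourceId optional metadata overriding columns of
#'   \code{x}.
#' @return list with \code{molecules} (a standardized
#'   \linkS4class{MoleculeSet}) and \code{rejected} (data.frame of inputs
#'   and reasons).
#' @export
standardizeMolecules <- function(x, family = NULL, activity = NULL,
                                 sourceId = NULL) {
  if (is(x, "MoleculeSet")) x <- as.data.frame(x)
  if (is.data.frame(x)) {
    family <- family %||% x$family
    activity <- activity %||% x$activity_nM %||% x$activity
    sourceId <- sourceId %||% x$source_id
    x <- x$smiles
  }
  n <- length(x)
  family <- recycleTo(family %||% NA_character_, n, "family")
  activity <- recycleTo(activity %||% NA_real_, n, "activity")
  sourceId <- recycleTo(sourceId %||% NA_character_, n, "sourceId")
  empty <- !nzchar(x) | is.na(x)
  status <- character(n)
  canon <- character(n)
  status[empty] <- "empty_input"
  if (any(!empty)) {
    res <- rdkitStandardize(x[!empty])
    status[!empty] <- vapply(res, `[[`, "", "status")
    canon[!empty] <- vapply(res, `[[`, "", "smiles")
  }
  keep <- status == "ok"
  list(
    molecules = MoleculeSet(canon[keep], family = family[keep],
                            activity = as.numeric(activity[keep]),
                            sourceId = sourceId[keep]),
    rejected = data.frame(input = x[!keep], reason = status[!keep],
                          stringsAsFactors = FALSE))
}

#' Compute the 20-descriptor panel
#'
#' Deterministic per-molecule descriptor computation in the fixed order of
#' \code{\link{descriptorNames}}. Molecules whose descriptors cannot be
#' computed yield NA rows and are reported in the \code{status} attribute so
#' they can be excluded downstream.
#'
#' @param x character SMILES vector or \linkS4class{MoleculeSet}.
#' @return data.frame with 20 numeric columns, one row per molecule;
#'   attributes \code{status} (per-row "ok"/failure reason), \code{elements}
#'   (per-row element symbols present) and \code{smiles}.
#' @export
computeDescriptors <- function(x) {
  smi <- if (is(x, "MoleculeSet")) smiles(x) else as.character(x)
  res <- rdkitDescriptors(smi)
  status <- vapply(res, `[[`, "", "status")
  dn <- descriptorNames()
  mat <- matrix(NA_real_, nrow = length(smi), ncol = length(dn),
                dimnames = list(NULL, dn))
  ok <- status == "ok"
  if (any(ok)) {
    mat[ok, ] <- do.call(rbind, lapply(res[ok], `[[`, "values"))
  }
  out <- as.data.frame(mat)
  attr(out, "status") <- status
  attr(out, "elements") <- vapply(res, `[[`, "", "elements")
  attr(out, "smiles") <- smi
  out
}

#' Library filter policy
#'
#' Drug-likeness bounds applied on library assembly, defaulting to the
#' extended rule-of-five cutoffs used throughout the pipeline: molecular
#' weight below 700 Da, logP in [-4, 6], at most 6 rotatable bonds, at most
#' 12 hydrogen-bond donors and acceptors, and a biologically relevant
#' element whitelist (C, N, O, F, S, P, Cl, Br, I; implicit hydrogens are
#' always allowed).
#'
#' @param mwMax,logpMin,logpMax,rotatableMax,hbdMax,hbaMax numeric bounds.
#' @param allowedElements character vector of allowed element symbols.
#' @return an object of class \code{filterPolicy}.
#' @export
filterPolicy <- function(mwMax = 700, logpMin = -4, logpMax = 6,
                         rotatableMax = 6, hbdMax = 12, hbaMax = 12,
                         allowedElements = c("C", "N", "O", "F", "S", "P",
                                             "Cl", "Br", "I")) {
  stopifnot(mwMax > 0, logpMin < logpMax)
  structure(list(mwMax = mwMax, logpMin = logpMin, logpMax = logpMax,
                 rotatableMax = rotatableMax, hbdMax = hbdMax,
                 hbaMax = hbaMax, allowedElements = allowedElements),
            class = "filterPolicy")
}

#' Apply library filters
#'
#' Retains molecules that satisfy every bound of the policy and contain
#' only whitelisted elements. Each rejected molecule is attributed to the
#' first rule it violates (fixed order: descriptor failure, molecular
#' weight, logP, rotatable bonds, HBD, HBA, element whitelist), so rule
#' counts plus the retained count always equal the input count.
#'
#' @param mols a \linkS4class{MoleculeSet}.
#' @param policy a \code{\link{filterPolicy}}.
#' @return list with \code{retained} (MoleculeSet) and \code{report}
#'   (data.frame of per-rule rejection counts; attributes \code{nInput},
#'   \code{nRetained}).
#' @export
applyLibraryFilters <- function(mols, policy = filterPolicy()) {
  stopifnot(is(mols, "MoleculeSet"), inherits(policy, "filterPolicy"))
  desc <- computeDescriptors(mols)
  status <- attr(desc, "status")
  elements <- strsplit(attr(desc, "elements"), " ", fixed = TRUE)
  n <- length(mols)
  reason <- rep(NA_character_, n)
  bad <- status != "ok"
  reason[bad] <- "descriptor_failure"
  chk <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  chk(!(desc$molecular_weight < policy$mwMax), "mw")
  chk(desc$logp < policy$logpMin | desc$logp > policy$logpMax, "logp")
  chk(desc$rotatable_bonds > policy$rotatableMax, "rotatable_bonds")
  chk(desc$hbd > policy$hbdMax, "hbd")
  chk(desc$hba > policy$hbaMax, "hba")
  offEl <- vapply(elements, function(e) {
    any(!e[nzchar(e)] %in% c(policy$allowedElements, "H"))
  }, logical(1))
  chk(offEl, "element")
  keep <- is.na(reason)
  rules <- c("descriptor_failure", "mw", "logp", "rotatable_bonds",
             "hbd", "hba", "element")
  report <- data.frame(rule = rules,
                       rejected = vapply(rules, function(r) {
                         sum(reason == r, na.rm = TRUE)
                       }, integer(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "nInput") <- n
  attr(report, "nRetained") <- sum(keep)
  list(retained = mols[keep], report = report)
}

#' Morgan fingerprints for a molecule set
#'
#' Circular-substructure hash fingerprints (radius 2, folded to 2048 bits
#' by default), deterministic for a given canonical molecule and parameter
#' pair.
#'
#' @param x character SMILES or \linkS4class{MoleculeSet}.
#' @param radius Morgan radius.
#' @param nBits folded bit-vector length.
#' @return a \linkS4class{FingerprintSet}.
#' @export
morganFingerprints <- function(x, radius = 2L, nBits = 2048L) {
  smi <- if (is(x, "MoleculeSet")) smiles(x) else as.character(x)
  fps <- rdkitFingerprint(smi, radius = radius, nBits = nBits)
  bad <- vapply(fps, is.null, logical(1))
  if (any(bad)) {
    stop(sprintf("unparsable SMILES in fingerprint input: %s",
                 paste(utils::head(smi[bad], 3), collapse = ", ")))
  }
  new("FingerprintSet", bits = fps, radius = as.integer(radius),
      nBits = as.integer(nBits), smiles = smi)
}

#' Tanimoto similarity between fingerprints
#'
#' |A intersect B| / |A union B| over on-bit sets; symmetric, in [0, 1],
#' and 1 for identical fingerprints (two empty fingerprints are treated as
#' identical). Both arguments must share radius and bit length.
#'
#' @param a,b \linkS4class{FingerprintSet} objects.
#' @return numeric similarity matrix of dimension length(a) x length(b);
#'   dropped to a scalar when both sets have length 1.
#' @export
tanimoto <- function(a, b) {
  stopifnot(is(a, "FingerprintSet"), is(b, "FingerprintSet"))
  if (a@radius != b@radius || a@nBits != b@nBits) {
    stop(sprintf(
      "fingerprint parameters differ: (radius %d, %d bits) vs (radius %d, %d bits)",
      a@radius, a@nBits, b@radius, b@nBits))
  }
  m <- matrix(0, length(a), length(b))
  for (i in seq_along(a@bits)) {
    ai <- a@bits[[i]]
    for (j in seq_along(b@bits)) {
      bj <- b@bits[[j]]
      un <- length(union(ai, bj))
      m[i, j] <- if (un == 0L) 1 else length(intersect(ai, bj)) / un
    }
  }
  if (length(a) == 1L && length(b) == 1L) m[1, 1] else m
}

#' Maximum Tanimoto similarity to a reference set
#'
#' For each query molecule, the maximum pairwise Tanimoto similarity over
#' the reference set and the first reference attaining it (ties broken by
#' first occurrence).
#'
#' @param x query molecules (SMILES or \linkS4class{MoleculeSet}).
#' @param refs non-empty reference molecules.
#' @param radius,nBits Morgan fingerprint parameters.
#' @return data.frame with columns \code{smiles}, \code{score},
#'   \code{nearest}.
#' @export
maxSimilarityToReference <- function(x, refs, radius = 2L, nBits = 2048L) {
  refSmi <- if (is(refs, "MoleculeSet")) smiles(refs) else as.character(refs)
  if (!length(refSmi)) stop("reference set is empty")
  fq <- morganFingerprints(x, radius, nBits)
  fr <- morganFingerprints(refSmi, radius, nBits)
  sim <- tanimoto(fq, fr)
  sim <- matrix(sim, nrow = length(fq))
  idx <- apply(sim, 1L, which.max)
  data.frame(smiles = fq@smiles,
             score = sim[cbind(seq_len(nrow(sim)), idx)],
             nearest = refSmi[idx], stringsAsFactors = FALSE)
}

# ------------------------------------------------------------------------ I/O

#' Read a SMILES line file
#'
#' Whitespace-separated \code{.smi} dialect: first field is the SMILES,
#' optional remainder is a name.
#'
#' @param path file path.
#' @return data.frame with columns \code{smiles} and \code{name}.
#' @export
readSmiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  name <- trimws(sub("^\\S+", "", lines))
  data.frame(smiles = parts, name = ifelse(nzchar(name), name,
                                           NA_character_),
             stringsAsFactors = FALSE)
}

#' Write a SMILES line file
#' @param x character SMILES or \linkS4class{MoleculeSet}.
#' @param path output path.
#' @param names optional name column.
#' @export
writeSmiles <- function(x, path, names = NULL) {
  smi <- if (is(x, "MoleculeSet")) smiles(x) else as.character(x)
  out <- if (is.null(names)) smi else paste(smi, names)
  writeLines(out, path)
  invisible(path)
}

#' Read a molecule CSV (smiles, family, activity_nM)
#' @param path file path.
#' @return a \linkS4class{MoleculeSet} (not standardized).
#' @export
readMoleculeCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) stop("CSV must have a 'smiles' column")
  MoleculeSet(df$smiles,
              family = df$family %||% NA_character_,
              activity = as.numeric(df$activity_nM %||% NA_real_),
              sourceId = df$source_id %||% NA_character_)
}

#' Write a molecule CSV (smiles, family, activity_nM, source_id)
#' @param mols a \linkS4class{MoleculeSet}.
#' @param path output path.
#' @export
writeMoleculeCsv <- function(mols, path) {
  utils::write.csv(as.data.frame(mols), path, row.names = FALSE)
  invisible(path)
}

#' Write a descriptor matrix as CSV in the fixed column order
#' @param desc result of \code{\link{computeDescriptors}}.
#' @param path output path.
#' @export
writeDescriptorCsv <- function(desc, path) {
  out <- cbind(data.frame(smiles = attr(desc, "smiles"),
                          stringsAsFactors = FALSE),
               desc[descriptorNames()])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
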