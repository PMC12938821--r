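# Bridge to the bundled RDKit helper (inst/python/rdkit_tools.py).
#
# All chemistry primitives that need a real cheminformatics kernel --
# SMILES parsing/canonicalization, tautomer normalization, the descriptor
# panel, Morgan fingerprints -- are delegated to RDKit through a batched
# subprocess call. Results are memoized per session so repeated queries for
# the same SMILES (common in decode-retry loops) cost nothing.

.kf_env <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for RDKit calls
#'
#' The interpreter can be overridden with \code{options(kinoforge.python=)};
#' by default the first \code{python} on the PATH is used and is expected to
#' have \code{rdkit} importable.
#'
#' @return path to the interpreter.
#' @export
kfPython <- function() {
  p <- getOption("kinoforge.python", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) {
    stop("no 'python' interpreter found; set options(kinoforge.python=)")
  }
  unname(p)
}

.rdkitScript <- function() {
  system.file("python", "rdkit_tools.py", package = "kinoforge",
              mustWork = TRUE)
}

# Run one batched helper call. `smiles` must not contain newlines.
.rdkitRun <- function(mode, smiles, args = character()) {
  stopifnot(is.character(smiles))
  if (any(grepl("[\n\t]", smiles))) {
    stop("SMILES input must not contain tabs or newlines")
  }
  inf <- tempfile("kf_in_"); outf <- tempfile("kf_out_")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  writeLines(smiles, inf)
  err <- system2(kfPython(), c(.rdkitScript(), mode, inf, outf, args),
                 stdout = FALSE, stderr = "")
  if (err != 0L) {
    stop(sprintf("RDKit helper failed (mode '%s', exit status %d)", mode, err))
  }
  res <- utils::read.delim(outf, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           na.strings = NULL, colClasses = "character")
  if (nrow(res) != length(smiles)) {
    stop("RDKit helper returned misaligned output")
  }
  res
}

# Memoized batch evaluation: `computeFun(todo)` must return a list aligned
# with `todo`; cached entries are reused across calls.
.cachedBatch <- function(cacheName, keys, computeFun) {
  cache <- .kf_env[[cacheName]]
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .kf_env[[cacheName]] <- cache
  }
  ekeys <- paste0("k", keys)
  miss <- !vapply(ekeys, exists, logical(1), envir = cache, inherits = FALSE)
  todo <- unique(keys[miss])
  if (length(todo)) {
    vals <- computeFun(todo)
    for (i in seq_along(todo)) {
      assign(paste0("k", todo[i]), vals[[i]], envir = cache)
    }
  }
  lapply(ekeys, get, envir = cache, inherits = FALSE)
}

# canonical standardization: list of (status, smiles) pairs
rdkitStandardize <- function(smiles) {
  .cachedBatch("std", smiles, function(todo) {
    res <- .rdkitRun("standardize", todo)
    lapply(seq_len(nrow(res)), function(i) {
      list(status = res$status[i], smiles = res$smiles[i])
    })
  })
}

# validity check: list of (valid, smiles) pairs; `smiles` is the canonical
# form of parseable input
rdkitValidate <- function(smiles) {
  .cachedBatch("val", smiles, function(todo) {
    res <- .rdkitRun("validate", todo)
    lapply(seq_len(nrow(res)), function(i) {
      list(valid = res$valid[i] == "1", smiles = res$smiles[i])
    })
  })
}

# descriptor panel: list of (status, values [named numeric], elements)
rdkitDescriptors <- function(smiles) {
  .cachedBatch("desc", smiles, function(todo) {
    res <- .rdkitRun("descriptors", todo)
    dn <- descriptorNames()
    lapply(seq_len(nrow(res)), function(i) {
      if (res$status[i] != "ok") {
        return(list(status = res$status[i], values = NULL, elements = ""))
      }
      v <- as.numeric(unlist(res[i, dn], use.names = FALSE))
      names(v) <- dn
      list(status = "ok", values = v, elements = res$elements[i])
    })
  })
}

# Morgan fingerprints: list of integer vectors of on-bit indices (0-based),
# or NULL for unparsable input
rdkitFingerprint <- function(smiles, radius = 2L, nBits = 2048L) {
  cacheName <- sprintf("fp_%d_%d", radius, nBits)
  .cachedBatch(cacheName, smiles, function(todo) {
    res <- .rdkitRun("fingerprint", todo,
                     c("--radius", radius, "--nbits", nBits))
    lapply(seq_len(nrow(res)), function(i) {
      if (res$status[i] != "ok") return(NULL)
      if (!nzchar(res$bits[i])) return(integer(0))
      as.integer(strsplit(res$bits[i], ",", fixed = TRUE)[[1]])
    })
  })
}
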