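#' @include AllClasses.R
NULL

# Token regex: bracket atoms, two-character halogens, stereo marker '@@'
# and two-digit ring closures are atomic; everything else is a single
# character.
.TOKEN_RE <- "\\[[^]]*\\]|Cl|Br|@@|%[0-9]{2}|."

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into vocabulary tokens. Multi-character units --
#' bracket atoms (\code{[nH]}, \code{[C@@H]}, ...), \code{Cl}, \code{Br},
#' \code{@@} and two-digit ring closures (\code{\%12}) -- are kept atomic
#' so that \code{"CCl"} tokenizes as \code{C}, \code{Cl} rather than
#' \code{C}, \code{C}, \code{l}. Tokenization is lossless:
#' \code{detokenize(tokenizeSmiles(s)) == s}.
#'
#' @param s a single SMILES string.
#' @return character vector of tokens.
#' @export
tokenizeSmiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) return(character(0))
  regmatches(s, gregexpr(.TOKEN_RE, s))[[1]]
}

#' Reassemble a SMILES string from tokens
#' @param tokens character vector of tokens.
#' @return the concatenated string.
#' @export
detokenize <- function(tokens) paste(tokens, collapse = "")

#' Build a token vocabulary from a corpus
#'
#' Collects all tokens occurring in the corpus, prepends the special tokens
#' (\code{<pad>}, \code{<sos>}, \code{<eos>}) and fixes the maximum
#' sequence length. Corpus strings longer than \code{maxLength} tokens are
#' rejected and reported in the \code{rejected} attribute.
#'
#' @param corpus character vector of SMILES (or a
#'   \linkS4class{MoleculeSet}).
#' @param maxLength maximum token-sequence length; defaults to the longest
#'   corpus string.
#' @return a \linkS4class{TokenVocabulary}; attribute \code{rejected} lists
#'   over-long strings.
#' @export
buildVocabulary <- function(corpus, maxLength = NULL) {
  if (is(corpus, "MoleculeSet")) corpus <- smiles(corpus)
  stopifnot(length(corpus) > 0L)
  tokList <- lapply(corpus, tokenizeSmiles)
  lens <- lengths(tokList)
  if (is.null(maxLength)) maxLength <- max(lens)
  keep <- lens <= maxLength
  toks <- sort(unique(unlist(tokList[keep])))
  vocab <- new("TokenVocabulary",
               tokens = c("<pad>", "<sos>", "<eos>", toks),
               maxLength = as.integer(maxLength))
  attr(vocab, "rejected") <- corpus[!keep]
  vocab
}

# Encode SMILES as an integer index matrix (n x (maxLength + 1)); each row
# is the token indices followed by <eos> then <pad>. Unknown tokens error.
vocabIndices <- function(vocab, smi) {
  stopifnot(is(vocab, "TokenVocabulary"))
  L <- vocab@maxLength + 1L
  pad <- 1L; eos <- 3L
  out <- matrix(pad, nrow = length(smi), ncol = L)
  for (i in seq_along(smi)) {
    toks <- tokenizeSmiles(smi[i])
    if (length(toks) > vocab@maxLength) {
      stop(sprintf("SMILES exceeds vocabulary maxLength (%d): '%s'",
                   vocab@maxLength, smi[i]))
    }
    idx <- match(toks, vocab@tokens)
    if (anyNA(idx)) {
      stop(sprintf("out-of-vocabulary token '%s' in '%s'",
                   toks[which(is.na(idx))[1]], smi[i]))
    }
    if (length(idx)) out[i, seq_along(idx)] <- idx
    out[i, length(toks) + 1L] <- eos
  }
  out
}

# Convert an index row back into a string: tokens up to the first <eos>,
# specials dropped.
indicesToSmiles <- function(vocab, idx) {
  eosAt <- which(idx == 3L)
  if (length(eosAt)) idx <- idx[seq_len(eosAt[1] - 1L)]
  idx <- idx[idx > 3L]
  detokenize(vocab@tokens[idx])
}

#' Character-length filter for decoded SMILES
#'
#' Strings whose character count is below \code{minLen} are discarded
#' (default 10), excluding trivial or non-drug-like outputs; length exactly
#' \code{minLen} is retained.
#'
#' @param smiles character vector.
#' @param minLen minimum length retained.
#' @return logical vector, TRUE for retained strings.
#' @export
lengthFilter <- function(smiles, minLen = 10L) {
  !is.na(smiles) & nchar(smiles) >= minLen
}
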