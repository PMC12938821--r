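#' @include utils.R
NULL

#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @export
setGeneric("molFamily", function(x) standardGeneric("molFamily"))

#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))

#' Latent dimensionality of an embedding model
#' @param model an embedding model (e.g. a \linkS4class{VaeModel}).
#' @return integer latent dimension.
#' @export
setGeneric("latentDim", function(model) standardGeneric("latentDim"))

#' Deterministic latent encoding
#'
#' Maps molecules to their posterior-mean latent vectors. Any object that
#' implements \code{encodeLatent}, \code{decodeDraws} and \code{latentDim}
#' satisfies the pluggable-embedding contract and can stand in for the
#' built-in autoencoder throughout the pipeline.
#'
#' @param model an embedding model.
#' @param x a character vector of SMILES or a \linkS4class{MoleculeSet}.
#' @param ... passed to methods.
#' @return numeric matrix, one row per molecule.
#' @export
setGeneric("encodeLatent", function(model, x, ...) {
  standardGeneric("encodeLatent")
})

#' Stochastic decoding draws from a latent vector
#'
#' Draws \code{n} candidate strings from the decoder distribution at a fixed
#' latent point; draws consume the current RNG stream.
#'
#' @param model an embedding model.
#' @param z numeric latent vector.
#' @param n number of draws.
#' @param ... e.g. \code{temperature}.
#' @return character vector of length \code{n} (raw, possibly invalid SMILES).
#' @export
setGeneric("decodeDraws", function(model, z, n, ...) {
  standardGeneric("decodeDraws")
})

#' @export
setGeneric("kalScore", function(model, x, ...) standardGeneric("kalScore"))

#' @export
setGeneric("featureImportances", function(model, ...) {
  standardGeneric("featureImportances")
})
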