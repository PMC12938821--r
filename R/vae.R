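#' @include vocab.R
NULL

# One-hot design matrix from an index matrix: n x (L * V), position-major
# blocks of width V.
.oneHot <- function(idx, V) {
  n <- nrow(idx); L <- ncol(idx)
  X <- matrix(0, n, L * V)
  off <- (rep(seq_len(L), each = n) - 1L) * V
  X[cbind(rep(seq_len(n), L), off + as.vector(idx))] <- 1
  X
}

# Row-wise softmax over position blocks of width V applied to an n x (L*V)
# logit matrix; numerically stabilized.
.blockSoftmax <- function(logits, L, V) {
  n <- nrow(logits)
  P <- matrix(0, n, L * V)
  for (p in seq_len(L)) {
    cols <- ((p - 1L) * V + 1L):(p * V)
    b <- logits[, cols, drop = FALSE]
    b <- b - apply(b, 1L, max)
    e <- exp(b)
    P[, cols] <- e / rowSums(e)
  }
  P
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Forward pass; returns intermediates needed for backprop.
.vaeForward <- function(params, X, eps = NULL) {
  H <- tanh(sweep(X %*% params$W1, 2L, params$b1, "+"))
  mu <- sweep(H %*% params$Wm, 2L, params$bm, "+")
  lv <- sweep(H %*% params$Wv, 2L, params$bv, "+")
  lv <- pmin(pmax(lv, -10), 10)  # keep exp(lv) sane
  z <- if (is.null(eps)) mu else mu + eps * exp(lv / 2)
  Hd <- tanh(sweep(z %*% params$W2, 2L, params$b2, "+"))
  logits <- sweep(Hd %*% params$W3, 2L, params$b3, "+")
  list(H = H, mu = mu, lv = lv, z = z, Hd = Hd, logits = logits)
}

# Mean-per-sample loss and gradients for one batch. Reconstruction is the
# summed cross-entropy over positions; KL is the usual diagonal-Gaussian
# divergence weighted by `beta`.
.vaeLossGrad <- function(params, X, idx, V, beta, eps) {
  n <- nrow(X); L <- ncol(idx)
  fw <- .vaeForward(params, X, eps)
  P <- .blockSoftmax(fw$logits, L, V)
  pTrue <- P[cbind(rep(seq_len(n), L),
                   (rep(seq_len(L), each = n) - 1L) * V + as.vector(idx))]
  recon <- -sum(log(pmax(matrix(pTrue, n, L), 1e-12))) / n
  kl <- -0.5 * sum(1 + fw$lv - fw$mu^2 - exp(fw$lv)) / n
  loss <- recon + beta * kl

  dlogits <- (P - X) / n
  gW3 <- t(fw$Hd) %*% dlogits
  gb3 <- colSums(dlogits)
  dHd <- (dlogits %*% t(params$W3)) * (1 - fw$Hd^2)
  gW2 <- t(fw$z) %*% dHd
  gb2 <- colSums(dHd)
  dz <- dHd %*% t(params$W2)
  dmu <- dz + beta * fw$mu / n
  dlv <- dz * eps * 0.5 * exp(fw$lv / 2) + beta * 0.5 * (exp(fw$lv) - 1) / n
  gWm <- t(fw$H) %*% dmu; gbm <- colSums(dmu)
  gWv <- t(fw$H) %*% dlv; gbv <- colSums(dlv)
  dH <- (dmu %*% t(params$Wm) + dlv %*% t(params$Wv)) * (1 - fw$H^2)
  gW1 <- t(X) %*% dH; gb1 <- colSums(dH)

  list(loss = loss, recon = recon, kl = kl,
       grads = list(W1 = gW1, b1 = gb1, Wm = gWm, bm = gbm, Wv = gWv,
                    bv = gbv, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3))
}

#' Train the character-level SMILES variational autoencoder
#'
#' Fits a position-factorized feed-forward VAE on tokenized SMILES by
#' full-batch (or minibatch) Adam with hand-computed gradients. The KL term
#' is linearly annealed from 0 to \code{klWeightMax} over the first
#' \code{klWarmup} epochs, which keeps tiny corpora trainable while still
#' shaping an approximately Gaussian latent cloud. Training is reproducible
#' under a fixed seed; a non-finite loss aborts with diagnostics.
#'
#' @param corpus standardized molecules (character SMILES or
#'   \linkS4class{MoleculeSet}).
#' @param latentDim latent dimensionality (default 196, matching the
#'   continuous embedding used throughout the pipeline; desk-scale runs
#'   typically use 8-32).
#' @param hiddenDim hidden-layer width.
#' @param epochs number of epochs.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size (default: full batch).
#' @param klWarmup epochs of linear KL annealing (default half of
#'   \code{epochs}).
#' @param klWeightMax final KL weight.
#' @param maxLength optional maximum token length (defaults to corpus max).
#' @param seed RNG seed for init, noise draws and shuffling.
#' @return a \linkS4class{VaeModel}.
#' @export
trainVae <- function(corpus, latentDim = 196L, hiddenDim = 128L,
                     epochs = 300L, lr = 2e-3, batchSize = Inf,
                     klWarmup = NULL, klWeightMax = 0.2,
                     maxLength = NULL, seed = 1L) {
  if (is(corpus, "MoleculeSet")) corpus <- smiles(corpus)
  stopifnot(length(corpus) >= 2L)
  klWarmup <- klWarmup %||% max(1L, floor(epochs / 2))
  vocab <- buildVocabulary(corpus, maxLength)
  if (length(attr(vocab, "rejected"))) {
    stop("corpus strings exceed maxLength: ",
         paste(utils::head(attr(vocab, "rejected"), 3), collapse = ", "))
  }
  idx <- vocabIndices(vocab, corpus)
  V <- length(vocab@tokens); L <- ncol(idx); D <- L * V
  n <- nrow(idx)
  X <- .oneHot(idx, V)

  withSeed(seed, {
    gl <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))),
                                a, b)
    params <- list(W1 = gl(D, hiddenDim), b1 = numeric(hiddenDim),
                   Wm = gl(hiddenDim, latentDim), bm = numeric(latentDim),
                   Wv = gl(hiddenDim, latentDim) * 0.01,
                   bv = rep(-2, latentDim),
                   W2 = gl(latentDim, hiddenDim), b2 = numeric(hiddenDim),
                   W3 = gl(hiddenDim, D), b3 = numeric(D))
    state <- .adamInit(params)
    logRows <- vector("list", epochs)
    bs <- if (!is.finite(batchSize)) n else min(n, batchSize)
    for (ep in seq_len(epochs)) {
      beta <- klWeightMax * min(1, ep / klWarmup)
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      epLoss <- epRecon <- epKl <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1L, n)]
        eps <- matrix(stats::rnorm(length(rows) * latentDim),
                      length(rows), latentDim)
        lg <- .vaeLossGrad(params, X[rows, , drop = FALSE],
                           idx[rows, , drop = FALSE], V, beta, eps)
        if (!is.finite(lg$loss)) {
          stop(sprintf(
            "non-finite VAE loss at epoch %d (recon %.3g, kl %.3g); lower lr",
            ep, lg$recon, lg$kl))
        }
        upd <- .adamStep(params, lg$grads, state, lr)
        params <- upd$params; state <- upd$state
        epLoss <- epLoss + lg$loss; epRecon <- epRecon + lg$recon
        epKl <- epKl + lg$kl; nb <- nb + 1L
      }
      logRows[[ep]] <- data.frame(epoch = ep, loss = epLoss / nb,
                                  recon = epRecon / nb, kl = epKl / nb,
                                  klWeight = beta)
    }
    new("VaeModel", vocab = vocab, latentDim = as.integer(latentDim),
        hiddenDim = as.integer(hiddenDim), params = params,
        trainingLog = do.call(rbind, logRows),
        config = list(epochs = epochs, lr = lr, batchSize = bs,
                      klWarmup = klWarmup, klWeightMax = klWeightMax),
        seed = as.integer(seed))
  })
}

#' @describeIn trainVae deterministic posterior-mean encoding of molecules.
#' @param model a \linkS4class{VaeModel}.
#' @param x character SMILES or \linkS4class{MoleculeSet}.
#' @param ... unused.
#' @export
setMethod("encodeLatent", "VaeModel", function(model, x, ...) {
  if (is(x, "MoleculeSet")) x <- smiles(x)
  idx <- vocabIndices(model@vocab, x)
  X <- .oneHot(idx, length(model@vocab@tokens))
  fw <- .vaeForward(model@params, X, eps = NULL)
  Z <- fw$mu
  rownames(Z) <- x
  Z
})

#' @describeIn trainVae stochastic decoding: \code{n} temperature-sampled
#'   token sequences drawn at the fixed latent point \code{z}.
#' @param z numeric latent vector.
#' @param n number of draws.
#' @param temperature softmax temperature.
#' @export
setMethod("decodeDraws", "VaeModel", function(model, z, n,
                                              temperature = 1.0, ...) {
  stopifnot(length(z) == model@latentDim)
  V <- length(model@vocab@tokens)
  L <- model@vocab@maxLength + 1L
  # decoder-only forward from z
  Hd <- tanh(model@params$b2 + as.vector(z %*% model@params$W2))
  logits <- model@params$b3 + as.vector(Hd %*% model@params$W3)
  draws <- matrix(0L, n, L)
  for (p in seq_len(L)) {
    lp <- logits[((p - 1L) * V + 1L):(p * V)] / temperature
    lp <- lp - max(lp)
    e <- exp(lp)
    draws[, p] <- sample.int(V, n, replace = TRUE, prob = e / sum(e))
  }
  vapply(seq_len(n), function(i) {
    indicesToSmiles(model@vocab, draws[i, ])
  }, character(1))
})

#' Decode a latent vector with validity retries
#'
#' Implements the decode-retry protocol: the decoder is sampled up to
#' \code{policy@maxAttempts} times at the fixed latent point; the first
#' draw that parses as a valid molecule and whose canonical SMILES is at
#' least \code{policy@minSmilesLength} characters long is returned. If
#' valid draws occur but all are too short the vector is classified
#' \code{length_filtered}; if no draw is valid, \code{decode_failed}.
#' Draws are generated in one batch (equivalent in distribution to
#' sequential retries) and validated through the chemistry back end.
#'
#' @param model an embedding model implementing \code{\link{decodeDraws}}.
#' @param z numeric latent vector.
#' @param policy a \linkS4class{DecodePolicy}.
#' @return list with \code{smiles} (canonical SMILES or NA), \code{status}
#'   ("ok", "length_filtered" or "decode_failed") and \code{attempts} (index
#'   of the accepted draw, or \code{maxAttempts} when none was accepted).
#' @export
decodeWithRetries <- function(model, z, policy = decodePolicy()) {
  stopifnot(is(policy, "DecodePolicy"))
  draws <- withSeed(policy@seed,
                    decodeDraws(model, z, policy@maxAttempts,
                                temperature = policy@temperature))
  .acceptDraws(draws, policy)
}

# shared accept/reject logic over a fixed vector of decoder draws
.acceptDraws <- function(draws, policy) {
  nonEmpty <- nzchar(draws)
  valid <- logical(length(draws))
  canon <- rep(NA_character_, length(draws))
  if (any(nonEmpty)) {
    res <- rdkitValidate(draws[nonEmpty])
    valid[nonEmpty] <- vapply(res, `[[`, logical(1), "valid")
    canon[nonEmpty] <- vapply(res, `[[`, "", "smiles")
  }
  okLen <- valid & lengthFilter(canon, policy@minSmilesLength)
  if (any(okLen)) {
    i <- which(okLen)[1]
    list(smiles = canon[i], status = "ok", attempts = i)
  } else if (any(valid)) {
    list(smiles = NA_character_, status = "length_filtered",
         attempts = policy@maxAttempts)
  } else {
    list(smiles = NA_character_, status = "decode_failed",
         attempts = policy@maxAttempts)
  }
}

# Batched decode-with-retries over the rows of Zs: draws are generated
# sequentially (identical RNG stream to per-row decodeWithRetries calls)
# but validated in a single back-end batch.
.decodeBatch <- function(model, Zs, policy) {
  n <- nrow(Zs)
  drawList <- vector("list", n)
  gen <- function() {
    for (i in seq_len(n)) {
      drawList[[i]] <<- decodeDraws(model, Zs[i, ], policy@maxAttempts,
                                    temperature = policy@temperature)
    }
  }
  withSeed(policy@seed, gen())
  uniq <- unique(unlist(drawList))
  uniq <- uniq[nzchar(uniq)]
  if (length(uniq)) invisible(rdkitValidate(uniq))  # warm the cache
  lapply(drawList, .acceptDraws, policy = policy)
}

#' Exact-reconstruction rate of a trained autoencoder
#'
#' Fraction of molecules whose greedy (argmax) decode of the posterior-mean
#' encoding reproduces the input string exactly; an overfit sanity metric
#' for toy corpora.
#'
#' @param model a \linkS4class{VaeModel}.
#' @param x molecules to check.
#' @return fraction in [0, 1].
#' @export
reconstructionRate <- function(model, x) {
  if (is(x, "MoleculeSet")) x <- smiles(x)
  Z <- encodeLatent(model, x)
  V <- length(model@vocab@tokens)
  L <- model@vocab@maxLength + 1L
  hits <- vapply(seq_along(x), function(i) {
    Hd <- tanh(model@params$b2 + as.vector(Z[i, ] %*% model@params$W2))
    logits <- model@params$b3 + as.vector(Hd %*% model@params$W3)
    draw <- vapply(seq_len(L), function(p) {
      which.max(logits[((p - 1L) * V + 1L):(p * V)])
    }, integer(1))
    identical(indicesToSmiles(model@vocab, draw), x[i])
  }, logical(1))
  mean(hits)
}
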