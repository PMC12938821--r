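#' @include gp.R
NULL

#' KAL objective over latent space
#'
#' Wraps an embedding model and a trained KAL classifier into the black-box
#' objective maximized by Bayesian optimization: a latent vector is decoded
#' under the retry policy and the decoded molecule's KAL score is returned.
#' Latent vectors that fail to decode score 0 by default (no molecule, no
#' kinase likeness); \code{undecodable = "skip"} returns NA so the step is
#' logged and excluded from the surrogate instead.
#'
#' @param vae an embedding model (see \code{\link{encodeLatent}}).
#' @param kalModel a trained \linkS4class{KalModel}.
#' @param policy a \linkS4class{DecodePolicy}.
#' @param undecodable "zero" or "skip".
#' @return function(z) returning a score in [0, 1] (or NA), with the
#'   decoded SMILES and attempts attached as attributes.
#' @export
makeKalObjective <- function(vae, kalModel, policy = decodePolicy(),
                             undecodable = c("zero", "skip")) {
  undecodable <- match.arg(undecodable)
  function(z) {
    dec <- decodeWithRetries(vae, z, policy)
    if (dec$status != "ok") {
      val <- if (undecodable == "zero") 0 else NA_real_
      return(structure(val, smiles = NA_character_,
                       attempts = dec$attempts, status = dec$status))
    }
    kal <- suppressWarnings(kalScore(kalModel, dec$smiles))
    structure(as.numeric(kal), smiles = dec$smiles,
              attempts = dec$attempts, status = "ok")
  }
}

#' Run KAL-guided Bayesian optimization over latent space
#'
#' Sequential model-based search: initialize with uniform probes in the
#' search box (unbiased mode) optionally preceded by encoded seed vectors
#' (biased mode; seeds are scored and enter the surrogate before any
#' acquisition step), then iterate propose / evaluate / refit. Kernel
#' hyperparameters are re-optimized by maximum marginal likelihood every
#' \code{config@refitPeriod} steps (the factorization is simply updated
#' with fixed hyperparameters in between). The run stops at
#' \code{config@maxSteps} acquisition steps or when the best score improves
#' by less than \code{config@plateauTol} over \code{config@plateauWindow}
#' consecutive steps. Histories larger than \code{config@gpCap} are
#' refit on the incumbent best plus the most recent points.
#'
#' @param objective function(z) -> score in [0, 1] (NA skips the step);
#'   see \code{\link{makeKalObjective}}.
#' @param config a \linkS4class{BoConfig}.
#' @param seeds optional matrix of seed latent vectors evaluated before the
#'   random initialization (biased mode).
#' @return a \linkS4class{BoRun}; when the objective attaches decoded
#'   SMILES, the per-evaluation decode ledger is populated.
#' @export
runBo <- function(objective, config, seeds = NULL) {
  stopifnot(is(config, "BoConfig"))
  d <- length(config@lower)
  withSeed(config@seed, {
    Zinit <- matrix(stats::runif(config@nInitRandom * d, config@lower,
                                 config@upper),
                    ncol = d, byrow = TRUE)
    if (!is.null(seeds)) {
      seeds <- as.matrix(seeds)
      stopifnot(ncol(seeds) == d)
      Zinit <- rbind(seeds, Zinit)
    }
    Z <- Zinit
    hist <- vector("list", nrow(Zinit) + config@maxSteps)
    evalOne <- function(z, phase, step) {
      val <- tryCatch(objective(z), error = function(e) {
        structure(NA_real_, status = paste("objective_error:",
                                           conditionMessage(e)))
      })
      data.frame(phase = phase, step = step, score = as.numeric(val),
                 smiles = attr(val, "smiles") %||% NA_character_,
                 attempts = attr(val, "attempts") %||% NA_integer_,
                 status = attr(val, "status") %||% "ok",
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(Zinit))) {
      ph <- if (!is.null(seeds) && i <= nrow(seeds)) "seed" else "init"
      hist[[i]] <- evalOne(Zinit[i, ], ph, 0L)
    }
    nInit <- nrow(Zinit)
    gp <- NULL
    stopReason <- "max_steps"
    bestTraj <- cummax(ifelse(is.na(vapply(hist[seq_len(nInit)],
                                           `[[`, 0, "score")), -Inf,
                              vapply(hist[seq_len(nInit)], `[[`, 0,
                                     "score")))
    nEval <- nInit
    for (step in seq_len(config@maxSteps)) {
      scores <- vapply(hist[seq_len(nEval)], `[[`, 0, "score")
      usable <- which(!is.na(scores))
      if (length(usable) >= 2L) {
        sub <- usable
        if (length(sub) > config@gpCap) {
          bestIdx <- usable[which.max(scores[usable])]
          sub <- unique(c(bestIdx,
                          utils::tail(usable, config@gpCap - 1L)))
        }
        refit <- is.null(gp) || (step - 1L) %% config@refitPeriod == 0L
        gp <- if (refit) {
          fitGp(Z[sub, , drop = FALSE], scores[sub])
        } else {
          p <- exp(gp@logParams)
          fitGp(Z[sub, , drop = FALSE], scores[sub],
                lengthscale = p[1], signalSd = p[2], noiseSd = p[3],
                optimize = FALSE)
        }
        zNext <- proposeNext(gp, config, best = max(scores[usable]))
        # repeated proposal (within tolerance) -> jittered re-proposal
        dmin <- min(sqrt(rowSums(sweep(Z, 2L, zNext)^2)))
        if (dmin < 1e-8) {
          span <- config@upper - config@lower
          zNext <- pmin(pmax(zNext + stats::rnorm(d, sd = 0.01 * span),
                             config@lower), config@upper)
        }
      } else {
        zNext <- stats::runif(d, config@lower, config@upper)
      }
      Z <- rbind(Z, zNext)
      nEval <- nEval + 1L
      hist[[nEval]] <- evalOne(zNext, "step", step)
      sc <- hist[[nEval]]$score
      bestTraj <- c(bestTraj,
                    max(utils::tail(bestTraj, 1L), sc, na.rm = TRUE))
      if (step >= config@plateauWindow + 1L) {
        cur <- bestTraj[nEval]
        prev <- bestTraj[nEval - config@plateauWindow]
        if (is.finite(cur) && is.finite(prev) &&
            cur - prev < config@plateauTol) {
          stopReason <- "plateau"
          break
        }
      }
    }
    history <- do.call(rbind, hist[seq_len(nEval)])
    history$best <- bestTraj
    dimnames(Z) <- NULL
    decoded <- history[history$phase == "step" & !is.na(history$smiles),
                       c("step", "smiles", "score", "attempts")]
    rownames(decoded) <- NULL
    new("BoRun", history = history, Z = Z, stopReason = stopReason,
        decoded = decoded, config = config)
  })
}

#' Best-so-far trajectory of a run
#' @param run a \linkS4class{BoRun}.
#' @return numeric non-decreasing vector.
#' @export
bestTrajectory <- function(run) run@history$best
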