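# The sampling-encoding layer G1 (FCN + batch normalisation + biased ReLU),
# the L1 dose measure, and fixed sampling schemes.

#' Biased ReLU
#'
#' Elementwise \code{max(0, v - lambdaBias)}. The bias controls how many
#' components of the sampling code are driven to exactly zero, i.e. how many
#' angles receive no dose.
#'
#' @param v numeric vector/matrix
#' @param lambdaBias non-negative sparsity bias
#' @return same shape as \code{v}
#' @examples
#' biasedReLU(c(-1, 0.2, 0.5), 0.2)
#' @export
biasedReLU <- function(v, lambdaBias) {
  if (lambdaBias < 0) stop("lambdaBias must be >= 0")
  pmax(v - lambdaBias, 0)
}

.heUnif <- function(nOut, nIn) {
  lim <- sqrt(6 / nIn)
  matrix(runif(nOut * nIn, -lim, lim), nOut, nIn)
}

#' Initialise sampling-encoder parameters
#'
#' Two fully-connected stages (flattened m1 x m2 sinogram -> hidden -> m2)
#' with He-uniform weights, followed by per-component batch normalisation
#' (scale 1, shift 1 at initialisation, so the unbiased code's mean dose
#' starts near 0.7 and every practical dose target is reachable by raising
#' the bias) and the biased ReLU clamped at 1.
#'
#' @param geometry a \linkS4class{CTGeometry}
#' @param hidden hidden width of the FCN (default 256)
#' @param seed initialisation seed
#' @param lambdaBias initial sparsity bias (default 0; set by calibration)
#' @return an \linkS4class{EncoderParams}
#' @export
newEncoderParams <- function(geometry, hidden = 256L, seed = 0L,
                             lambdaBias = 0) {
  m1 <- geometry@nDetectors; m2 <- geometry@nAngles
  d <- m1 * m2
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  weights <- list(W1 = .heUnif(hidden, d), b1 = numeric(hidden),
                  W2 = .heUnif(m2, hidden), b2 = numeric(m2),
                  gamma = rep(1, m2), beta = rep(1, m2))
  new("EncoderParams", weights = weights,
      bnState = list(mean = numeric(m2), var = rep(1, m2)),
      lambdaBias = lambdaBias,
      dims = list(inputDim = d, hidden = as.integer(hidden),
                  m2 = m2, m1 = m1),
      seed = as.integer(seed))
}

.bnEps <- 1e-5

# Forward pass over a batch. `sinos` is a list of m1 x m2 matrices.
# mode "train" uses batch statistics (batch size >= 2 required), "eval"
# the running statistics. Returns the code matrix (m2 x B) and a cache for
# the backward pass; optionally the updated running statistics.
.encodeForward <- function(params, sinos, mode = c("eval", "train"),
                           momentum = 0.1) {
  mode <- match.arg(mode)
  w <- params@weights
  d <- params@dims$inputDim
  X <- vapply(sinos, function(s) {
    if (length(s) != d) stop("sinogram shape does not match encoder input")
    as.numeric(s)
  }, numeric(d))
  X <- matrix(X, nrow = d)
  B <- ncol(X)
  Z1 <- w$W1 %*% X + w$b1
  A1 <- pmax(Z1, 0)
  Z2 <- w$W2 %*% A1 + w$b2
  if (mode == "train") {
    if (B < 2L) stop("train-mode batch normalisation needs a batch of >= 2")
    mu <- rowMeans(Z2)
    va <- rowMeans((Z2 - mu)^2)
    runMean <- (1 - momentum) * params@bnState$mean + momentum * mu
    # running variance tracks the unbiased estimate, as is conventional,
    # so eval-mode codes match the train-time distribution
    runVar <- (1 - momentum) * params@bnState$var +
      momentum * va * B / (B - 1)
  } else {
    mu <- params@bnState$mean
    va <- params@bnState$var
    runMean <- NULL; runVar <- NULL
  }
  inv <- 1 / sqrt(va + .bnEps)
  Zh <- (Z2 - mu) * inv
  Zn <- w$gamma * Zh + w$beta
  E0 <- pmax(Zn - params@lambdaBias, 0)
  E <- pmin(E0, 1)
  list(E = E,
       cache = list(X = X, Z1 = Z1, A1 = A1, Zh = Zh, Zn = Zn, E0 = E0,
                    inv = inv, mode = mode, B = B, mu = mu, va = va),
       runMean = runMean, runVar = runVar)
}

# Backward pass: dE is m2 x B. Returns gradients for all encoder weights.
.encodeBackward <- function(params, cache, dE) {
  w <- params@weights
  m2 <- params@dims$m2
  B <- cache$B
  dE0 <- dE * (cache$E0 < 1)
  dZn <- dE0 * (cache$Zn > params@lambdaBias)
  dgamma <- rowSums(dZn * cache$Zh)
  dbeta <- rowSums(dZn)
  dZh <- dZn * w$gamma
  if (cache$mode == "train") {
    # standard batch-norm backward over the batch dimension
    dZ2 <- cache$inv * (dZh - rowMeans(dZh) -
                          cache$Zh * rowMeans(dZh * cache$Zh))
  } else {
    dZ2 <- dZh * cache$inv
  }
  dW2 <- dZ2 %*% t(cache$A1)
  db2 <- rowSums(dZ2)
  dA1 <- t(w$W2) %*% dZ2
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- dZ1 %*% t(cache$X)
  db1 <- rowSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       gamma = dgamma, beta = dbeta)
}

#' Produce a sampling code for a sinogram
#'
#' Runs the encoding layer: flatten, FCN, per-component batch
#' normalisation, biased ReLU, clamp at 1. The output has one entry per
#' projection angle, each in [0,1]. In \code{"eval"} mode the running BN
#' statistics are used and a single sinogram suffices; in \code{"train"}
#' mode supply a list of sinograms so batch statistics exist.
#'
#' @param params an \linkS4class{EncoderParams}
#' @param sino a \linkS4class{Sinogram}, or a list of them in train mode
#' @param mode "eval" (default) or "train"
#' @return a \linkS4class{ProjectionEncoding} (eval) or list of them (train)
#' @export
encodeProjections <- function(params, sino, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  single <- is(sino, "Sinogram")
  sinos <- if (single) list(sino@values) else
    lapply(sino, function(s) if (is(s, "Sinogram")) s@values else s)
  fw <- .encodeForward(params, sinos, mode)
  encs <- lapply(seq_len(ncol(fw$E)), function(j)
    projectionEncoding(fw$E[, j]))
  if (single) encs[[1]] else encs
}

#' Dose fraction of a sampling code
#'
#' The L1 norm of the code divided by the number of angles, so the
#' full-dose (all-ones) code scores exactly 1.
#'
#' @param encoding a \linkS4class{ProjectionEncoding}
#' @return numeric in [0,1]
#' @examples
#' doseFraction(projectionEncoding(rep(1, 90)))
#' @export
doseFraction <- function(encoding) {
  e <- if (is(encoding, "ProjectionEncoding")) encoding@e else encoding
  sum(abs(e)) / length(e)
}

#' Apply a sampling code to a sinogram
#'
#' Columnwise scaling: output column j equals \code{e_j} times input column
#' j. This is the differentiable path used inside the networks; the
#' all-ones code is the identity.
#'
#' @param sino a \linkS4class{Sinogram}
#' @param encoding a \linkS4class{ProjectionEncoding} of matching length
#' @return a \linkS4class{Sinogram}
#' @export
applyEncoding <- function(sino, encoding) {
  stopifnot(is(sino, "Sinogram"), is(encoding, "ProjectionEncoding"))
  if (length(encoding@e) != ncol(sino@values))
    stop("encoding length must equal the number of angles")
  sinogram(sweep(sino@values, 2, encoding@e, "*"), sino@geometry)
}

#' Equal-interval sampling scheme
#'
#' The conventional baseline: \code{k = round(m2 * gamma)} angles kept at
#' full dose, placed at indices \code{floor(j*m2/k)} for \code{j = 0..k-1}
#' (0-based), all other angles unmeasured. Its dose fraction is exactly
#' \code{k/m2}.
#'
#' @param m2 number of projection angles
#' @param gamma dose target in (0,1]
#' @return a \linkS4class{ProjectionEncoding}
#' @examples
#' doseFraction(equalIntervalEncoding(90, 1/3))
#' @export
equalIntervalEncoding <- function(m2, gamma) {
  if (m2 < 1) stop("m2 must be >= 1")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0,1]")
  k <- round(m2 * gamma)
  if (k == 0) stop("dose target rounds to zero kept angles")
  idx <- floor((0:(k - 1)) * m2 / k) + 1L
  e <- numeric(m2)
  e[idx] <- 1
  projectionEncoding(e)
}

#' Export an input-independent sampling scheme
#'
#' A deployable scheme cannot depend on the (not yet measured) sinogram, so
#' the per-sinogram eval-mode codes of a reference dataset are averaged.
#' With \code{binarize = TRUE} the \code{k = round(m2*gamma)} largest mean
#' entries are set to 1 and the rest to 0, yielding an angle subset at the
#' requested dose.
#'
#' @param params an \linkS4class{EncoderParams}
#' @param sinos non-empty list of \linkS4class{Sinogram}s
#' @param binarize keep only the top-k angles at full dose?
#' @param gamma dose target used for the top-k rule (required if binarize)
#' @return a \linkS4class{ProjectionEncoding}
#' @export
exportFixedEncoding <- function(params, sinos, binarize = FALSE,
                                gamma = NULL) {
  if (length(sinos) == 0) stop("dataset must be non-empty")
  encs <- encodeProjections(params, sinos, mode = "eval")
  if (is(encs, "ProjectionEncoding")) encs <- list(encs)
  m <- rowMeans(vapply(encs, function(x) x@e,
                       numeric(params@dims$m2)))
  if (binarize) {
    if (is.null(gamma)) stop("gamma is required when binarize = TRUE")
    k <- round(params@dims$m2 * gamma)
    if (k == 0) stop("dose target rounds to zero kept angles")
    keep <- order(m, decreasing = TRUE)[seq_len(k)]
    m <- numeric(length(m)); m[keep] <- 1
  }
  projectionEncoding(pmin(pmax(m, 0), 1))
}
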