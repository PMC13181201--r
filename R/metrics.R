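# Image-quality metrics and dose-difference tracking.

.asMat <- function(x) {
  if (is(x, "CTImage")) x@pixels
  else if (is(x, "Sinogram")) x@values
  else as.matrix(x)
}

#' Mean squared error
#' @param a,b images or sinograms of identical shape (CTImage, Sinogram or
#'   matrix)
#' @return non-negative scalar
#' @examples
#' imageMSE(matrix(0, 4, 4), matrix(0.1, 4, 4))
#' @export
imageMSE <- function(a, b) {
  a <- .asMat(a); b <- .asMat(b)
  if (!identical(dim(a), dim(b))) stop("shapes must match")
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' \code{10*log10(dataRange^2 / mse)}; identical inputs give \code{Inf}.
#'
#' @param a,b images of identical shape
#' @param dataRange dynamic range of the data (default 1, images in [0,1])
#' @return PSNR in dB (possibly \code{Inf})
#' @export
imagePSNR <- function(a, b, dataRange = 1) {
  if (dataRange <= 0) stop("dataRange must be > 0")
  m <- imageMSE(a, b)
  if (m == 0) return(Inf)
  10 * log10(dataRange^2 / m)
}

.gauss1d <- function(size = 11L, sigma = 1.5) {
  x <- seq(-(size - 1) / 2, (size - 1) / 2)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# separable "valid" convolution with a 1-D kernel applied to rows then cols
.sepValid <- function(x, g) {
  k <- length(g)
  n1 <- nrow(x) - k + 1L
  n2 <- ncol(x) - k + 1L
  tmp <- matrix(0, n1, ncol(x))
  for (a in seq_len(k))
    tmp <- tmp + g[a] * x[a:(a + n1 - 1L), , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (b in seq_len(k))
    out <- out + g[b] * tmp[, b:(b + n2 - 1L), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5) and the
#' standard stabilising constants K1 = 0.01, K2 = 0.03.
#'
#' @param a,b images of identical shape, min dimension >= 11
#' @param dataRange dynamic range (default 1)
#' @return scalar in [-1, 1]
#' @export
imageSSIM <- function(a, b, dataRange = 1) {
  a <- .asMat(a); b <- .asMat(b)
  if (!identical(dim(a), dim(b))) stop("shapes must match")
  if (min(dim(a)) < 11L) stop("image smaller than the 11x11 SSIM window")
  g <- .gauss1d()
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  mx <- .sepValid(a, g)
  my <- .sepValid(b, g)
  sxx <- .sepValid(a * a, g) - mx^2
  syy <- .sepValid(b * b, g) - my^2
  sxy <- .sepValid(a * b, g) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Absolute deviation of a code's dose from its target
#'
#' @param encoding a \linkS4class{ProjectionEncoding}
#' @param gamma dose target in (0, 1]
#' @return \code{abs(doseFraction(encoding) - gamma)}
#' @export
doseDifference <- function(encoding, gamma) {
  abs(doseFraction(encoding) - gamma)
}

#' Standard evaluation triple (plus dose terms when a code is in scope)
#'
#' @param a reconstructed image
#' @param b reference image
#' @param dataRange dynamic range (default 1)
#' @param encoding optional \linkS4class{ProjectionEncoding}
#' @param gamma optional dose target
#' @return named list with ssim, psnr, mse, dataRange and, when an encoding
#'   is given, doseFraction and doseDifference
#' @export
metricsReport <- function(a, b, dataRange = 1, encoding = NULL,
                          gamma = NULL) {
  out <- list(ssim = imageSSIM(a, b, dataRange),
              psnr = imagePSNR(a, b, dataRange),
              mse = imageMSE(a, b),
              dataRange = dataRange)
  if (!is.null(encoding)) {
    out$doseFraction <- doseFraction(encoding)
    if (!is.null(gamma)) out$doseDifference <- doseDifference(encoding, gamma)
  }
  out
}
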