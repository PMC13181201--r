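# Forward projection, sparse-sampling degradation physics, and filtered
# back-projection.

#' Discrete radon transform
#'
#' Ray-driven line integrals of the image with bilinear sampling along each
#' ray (step half a pixel), for the detector offsets and uniform [0, pi)
#' angles of the geometry. Linear in the image.
#'
#' @param image a \linkS4class{CTImage} (square)
#' @param geometry a \linkS4class{CTGeometry}
#' @return a \linkS4class{Sinogram}
#' @examples
#' g <- defaultGeometry(64, 60)
#' s <- radonTransform(sheppLoganPhantom(64), g)
#' dim(sinogramValues(s))
#' @export
radonTransform <- function(image, geometry) {
  stopifnot(is(image, "CTImage"), is(geometry, "CTGeometry"))
  px <- image@pixelSize
  vals <- cpp_radon(image@pixels, projectionAngles(geometry),
                    geometry@nDetectors, detectorPositions(geometry)[1],
                    geometry@detectorSpacing, px, px / 2, sqrt(2) * 1.05)
  sinogram(vals, geometry)
}

#' Ramp filter frequency response
#'
#' Discrete |omega| response on the FFT grid of length
#' \code{nextPow2(2*m1)}: zero at DC, symmetric (bin k equals bin N-k), and
#' maximal at the Nyquist bin. Units are cycles per sample.
#'
#' @param m1 number of detector bins (>= 2)
#' @return numeric vector of length \code{nextPow2(2*m1)}
#' @export
rampFilter <- function(m1) {
  if (m1 < 2) stop("m1 must be >= 2")
  N <- 2^ceiling(log2(2 * m1))
  k <- 0:(N - 1)
  pmin(k, N - k) / N
}

# Ramp-filter every column of a detector-profile matrix. Zero-pad to the
# FFT grid, multiply by the |omega| response, transform back, truncate and
# divide by the detector spacing (the continuous-frequency measure). The
# operation is self-adjoint: circular convolution with a real, even kernel,
# and the pad/truncate pair swap under transposition.
.filterColumns <- function(values, ds) {
  m1 <- nrow(values)
  r <- rampFilter(m1)
  N <- length(r)
  P <- rbind(values, matrix(0, N - m1, ncol(values)))
  Ff <- mvfft(P) * r
  fs <- Re(mvfft(Ff, inverse = TRUE)) / N
  fs[seq_len(m1), , drop = FALSE] / ds
}

#' Filtered back-projection
#'
#' Ramp-filters each projection in the frequency domain and back-projects
#' with linear interpolation at \eqn{t = x\cos\theta + y\sin\theta}, scaled
#' by \eqn{\pi/m_2}. Linear in the sinogram.
#'
#' @param sino a \linkS4class{Sinogram}
#' @param n output image side; default inferred from the detector spacing
#'   so that the image spans [-1,1]
#' @return a \linkS4class{CTImage}
#' @export
filteredBackprojection <- function(sino, n = NULL) {
  stopifnot(is(sino, "Sinogram"))
  g <- sino@geometry
  if (g@nAngles < 1L) stop("geometry must contain at least one angle")
  if (is.null(n)) n <- round(2 / g@detectorSpacing)
  n <- as.integer(n)
  px <- 2 / n
  fs <- .filterColumns(sino@values, g@detectorSpacing)
  img <- cpp_backproject(fs, projectionAngles(g), detectorPositions(g)[1],
                         g@detectorSpacing, n, px, pi / g@nAngles)
  ctImage(img, px)
}

# Adjoint of filteredBackprojection (gradient of the image with respect to
# the sinogram): back-projection adjoint followed by the (self-adjoint)
# ramp filtering.
.fbpAdjoint <- function(dimg, geometry, n) {
  g <- geometry
  px <- 2 / n
  dfs <- cpp_backproject_adj(dimg, projectionAngles(g),
                             detectorPositions(g)[1], g@detectorSpacing,
                             g@nDetectors, px, pi / g@nAngles)
  .filterColumns(dfs, g@detectorSpacing)
}

#' Additive log-domain degradation field of a sampling code
#'
#' Column j is the constant \eqn{-\ln(\max(e_j, \beta_{floor}))} broadcast
#' across detector bins: the additive degradation that per-angle dose
#' reduction contributes to the log-attenuation sinogram. The floor keeps
#' the field bounded where an angle receives (near) zero dose.
#'
#' @param encoding a \linkS4class{ProjectionEncoding} of length m2
#' @param geometry a \linkS4class{CTGeometry}
#' @param betaFloor minimum admissible sampling coefficient, in (0,1);
#'   default \code{exp(-10)}
#' @return a \linkS4class{DegradationField}
#' @export
degradationField <- function(encoding, geometry, betaFloor = exp(-10)) {
  stopifnot(is(encoding, "ProjectionEncoding"), is(geometry, "CTGeometry"))
  e <- encoding@e
  if (length(e) != geometry@nAngles)
    stop("encoding length must equal the number of angles")
  if (betaFloor <= 0 || betaFloor >= 1) stop("betaFloor must lie in (0,1)")
  col <- -log(pmax(e, betaFloor))
  vals <- matrix(col, nrow = geometry@nDetectors, ncol = geometry@nAngles,
                 byrow = TRUE)
  new("DegradationField", values = vals, betaFloor = betaFloor)
}

#' Simulate the measurement of a sparse-view acquisition
#'
#' Physics path of the sparse-sampling model: with noise off, the measured
#' log-attenuation sinogram is exactly the full-dose sinogram plus the
#' additive degradation field of the sampling code (superposition). With
#' noise on, independent Gaussian perturbations are added with per-entry
#' standard deviation \eqn{1/\sqrt{I_0\,\beta_j\,e^{-M_{ij}}}} (the
#' photon-statistics scale at the delivered per-angle dose), seeded.
#'
#' @param sino full-dose \linkS4class{Sinogram}
#' @param encoding a \linkS4class{ProjectionEncoding}
#' @param photon a \linkS4class{PhotonModel}
#' @param seed RNG seed for the noise draw
#' @param betaFloor floor for the sampling coefficient
#' @return a \linkS4class{Sinogram} of the degraded measurement
#' @export
measureSparse <- function(sino, encoding, photon = photonModel(),
                          seed = 0L, betaFloor = exp(-10)) {
  stopifnot(is(sino, "Sinogram"), is(encoding, "ProjectionEncoding"),
            is(photon, "PhotonModel"))
  fld <- degradationField(encoding, sino@geometry, betaFloor)
  out <- sino@values + fld@values
  if (photon@noiseEnabled) {
    beta <- pmax(encoding@e, betaFloor)
    counts <- photon@I0 *
      matrix(beta, nrow(out), ncol(out), byrow = TRUE) * exp(-sino@values)
    old <- .saveSeed(); on.exit(.restoreSeed(old))
    set.seed(as.integer(seed))
    out <- out + matrix(rnorm(length(out)), nrow(out)) / sqrt(counts)
  }
  sinogram(out, sino@geometry)
}
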