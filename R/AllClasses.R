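# S4 containers shared by all modules.

#' Parallel-beam acquisition geometry
#'
#' Describes the sampling of the sinogram: \code{nDetectors} bins along the
#' detector (spacing \code{detectorSpacing}, centred on the rotation axis) and
#' \code{nAngles} projection angles uniform on the half-open interval
#' \eqn{[0, \pi)}, angle \eqn{j} equal to \eqn{(j-1)\pi/m_2}.
#'
#' @slot nDetectors integer, number of detector bins (m1)
#' @slot nAngles integer, number of projection angles (m2)
#' @slot detectorSpacing numeric, physical units per detector bin
#' @export
setClass("CTGeometry",
  representation(nDetectors = "integer", nAngles = "integer",
                 detectorSpacing = "numeric"),
  validity = function(object) {
    if (length(object@nDetectors) != 1L || object@nDetectors < 2L)
      return("nDetectors must be a single integer >= 2")
    if (length(object@nAngles) != 1L || object@nAngles < 1L)
      return("nAngles must be a single integer >= 1")
    if (!is.finite(object@detectorSpacing) || object@detectorSpacing <= 0)
      return("detectorSpacing must be a positive number")
    TRUE
  })

#' Square attenuation image
#'
#' An n-by-n grid of attenuation values in [0,1]; pixel centres span
#' \eqn{[-1,1]^2} when \code{pixelSize} is the default \code{2/n}. Row index
#' increases downward.
#'
#' @slot pixels numeric matrix, n x n
#' @slot pixelSize physical units per pixel
#' @export
setClass("CTImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (nrow(object@pixels) != ncol(object@pixels))
      return("image must be square")
    if (!all(is.finite(object@pixels)))
      return("image values must be finite")
    if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
      return("pixelSize must be positive")
    TRUE
  })

#' Sinogram (projection matrix)
#'
#' An m1 x m2 matrix of log-attenuation line integrals; column j is the
#' projection at angle j of the attached geometry.
#'
#' @slot values numeric matrix m1 x m2
#' @slot geometry a \linkS4class{CTGeometry}
#' @export
setClass("Sinogram",
  representation(values = "matrix", geometry = "CTGeometry"),
  validity = function(object) {
    g <- object@geometry
    if (nrow(object@values) != g@nDetectors ||
        ncol(object@values) != g@nAngles)
      return("sinogram dimensions do not match geometry (m1 x m2)")
    if (!all(is.finite(object@values)))
      return("sinogram entries must be finite")
    TRUE
  })

#' Ellipse phantom specification
#'
#' A set of additive ellipses: centres in image coordinates ([-1,1]),
#' semi-axes in [0,1], rotation in radians and an additive attenuation value.
#' Rendering sums intensities of overlapping ellipses and clips to [0,1].
#'
#' @slot ellipses data.frame with columns cx, cy, a, b, phi, value
#' @export
setClass("PhantomSpec",
  representation(ellipses = "data.frame"),
  validity = function(object) {
    need <- c("cx", "cy", "a", "b", "phi", "value")
    if (!all(need %in% names(object@ellipses)))
      return(paste("ellipses must have columns", paste(need, collapse = ", ")))
    e <- object@ellipses
    if (nrow(e) > 0 && (any(e$a <= 0) || any(e$b <= 0)))
      return("semi-axes must be positive")
    TRUE
  })

#' Per-angle sampling code
#'
#' Length-m2 vector of per-angle dose fractions in [0,1]. The all-ones code
#' is the full-dose acquisition; the L1 norm divided by m2 is the dose
#' fraction.
#'
#' @slot e numeric vector with entries in [0,1]
#' @export
setClass("ProjectionEncoding",
  representation(e = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@e))) return("encoding entries must be finite")
    if (any(object@e < 0) || any(object@e > 1))
      return("encoding entries must lie in [0,1]")
    TRUE
  })

#' Photon-counting model
#'
#' Incident photon count per ray at full dose and a flag controlling whether
#' Gaussian photon-statistics noise is simulated.
#'
#' @slot I0 incident photons per ray (full dose)
#' @slot noiseEnabled logical
#' @export
setClass("PhotonModel",
  representation(I0 = "numeric", noiseEnabled = "logical"),
  validity = function(object) {
    if (!is.finite(object@I0) || object@I0 <= 0) return("I0 must be > 0")
    TRUE
  })

#' Additive log-domain degradation field
#'
#' Matrix of per-entry additive degradation \eqn{-\ln\beta(\theta,i)}
#' produced by per-angle dose reduction, bounded by the documented beta
#' floor.
#'
#' @slot values m1 x m2 matrix, entries in [0, -log(betaFloor)]
#' @slot betaFloor minimum admissible sampling coefficient
#' @export
setClass("DegradationField",
  representation(values = "matrix", betaFloor = "numeric"),
  validity = function(object) {
    if (object@betaFloor <= 0 || object@betaFloor >= 1)
      return("betaFloor must lie in (0,1)")
    lim <- -log(object@betaFloor) + 1e-12
    if (any(object@values < -1e-12) || any(object@values > lim))
      return("degradation entries must lie in [0, -log(betaFloor)]")
    TRUE
  })

# ---- network parameter groups -------------------------------------------

#' Sampling-encoder parameters (G1)
#'
#' Two fully-connected stages (flattened sinogram -> hidden -> m2), a
#' per-component batch-normalisation state and the sparsity bias of the
#' biased ReLU.
#'
#' @slot weights list W1, b1, W2, b2, gamma, beta
#' @slot bnState list mean, var (running statistics)
#' @slot lambdaBias non-negative sparsity bias
#' @slot dims list inputDim, hidden, m2, m1
#' @slot seed initialisation seed
#' @export
setClass("EncoderParams",
  representation(weights = "list", bnState = "list", lambdaBias = "numeric",
                 dims = "list", seed = "integer"),
  validity = function(object) {
    if (object@lambdaBias < 0) return("lambdaBias must be >= 0")
    TRUE
  })

#' Sinogram-recovery network parameters (G2')
#'
#' Five Conv+ReLU stages followed by five Deconv+ReLU stages, 64 channels,
#' 3x3 kernels, stride 1, no padding, with a global residual connection.
#'
#' @slot layers list of layer weight sets
#' @slot seed initialisation seed
#' @export
setClass("ProjReconParams",
  representation(layers = "list", seed = "integer"))

#' Image detail-restoration network parameters (G2'')
#'
#' U-Net style encoder/decoder (widths 32 to 512), three 3-stage skip paths,
#' a 1-channel bridging convolution and a 2x back-projection
#' super-resolution head.
#'
#' @slot layers list of layer weight sets
#' @slot seed initialisation seed
#' @export
setClass("ImageReconParams",
  representation(layers = "list", seed = "integer"))

#' Joint model checkpoint
#'
#' The three trained parameter groups plus the geometry and the
#' configuration they were trained under.
#'
#' @slot encoder \linkS4class{EncoderParams}
#' @slot projNet \linkS4class{ProjReconParams}
#' @slot imageNet \linkS4class{ImageReconParams}
#' @slot geometry \linkS4class{CTGeometry}
#' @slot config list, configuration echo
#' @export
setClass("JointModel",
  representation(encoder = "EncoderParams", projNet = "ProjReconParams",
                 imageNet = "ImageReconParams", geometry = "CTGeometry",
                 config = "list"))

# ---- constructors --------------------------------------------------------

#' Create a parallel-beam geometry
#'
#' @param nDetectors number of detector bins (m1)
#' @param nAngles number of projection angles (m2)
#' @param detectorSpacing physical units per bin
#' @return a \linkS4class{CTGeometry}
#' @export
ctGeometry <- function(nDetectors, nAngles, detectorSpacing) {
  new("CTGeometry", nDetectors = as.integer(nDetectors),
      nAngles = as.integer(nAngles),
      detectorSpacing = as.numeric(detectorSpacing))
}

#' Default geometry for an n x n image
#'
#' Detector count is the smallest odd integer covering the image diagonal
#' (\eqn{m_1 \ge n\sqrt2}), spacing equals the pixel size \code{2/n}.
#'
#' @param n image side length
#' @param nAngles number of projection angles
#' @return a \linkS4class{CTGeometry}
#' @export
defaultGeometry <- function(n, nAngles = 180L) {
  m1 <- ceiling(n * sqrt(2))
  if (m1 %% 2 == 0) m1 <- m1 + 1
  ctGeometry(m1, nAngles, 2 / n)
}

#' Create a CT image
#' @param pixels square numeric matrix
#' @param pixelSize physical units per pixel; default spans [-1,1]
#' @return a \linkS4class{CTImage}
#' @export
ctImage <- function(pixels, pixelSize = 2 / nrow(pixels)) {
  new("CTImage", pixels = pixels, pixelSize = pixelSize)
}

#' Create a sinogram
#' @param values m1 x m2 matrix
#' @param geometry a \linkS4class{CTGeometry}
#' @return a \linkS4class{Sinogram}
#' @export
sinogram <- function(values, geometry) {
  new("Sinogram", values = values, geometry = geometry)
}

#' Create a phantom specification
#' @param ellipses data.frame with columns cx, cy, a, b, phi, value
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(ellipses = data.frame(cx = numeric(), cy = numeric(),
                                              a = numeric(), b = numeric(),
                                              phi = numeric(),
                                              value = numeric())) {
  new("PhantomSpec", ellipses = ellipses)
}

#' Create a per-angle sampling code
#' @param e numeric vector with entries in [0,1]
#' @return a \linkS4class{ProjectionEncoding}
#' @export
projectionEncoding <- function(e) new("ProjectionEncoding", e = as.numeric(e))

#' Create a photon-counting model
#' @param I0 incident photons per ray at full dose
#' @param noiseEnabled simulate Gaussian photon noise?
#' @return a \linkS4class{PhotonModel}
#' @export
photonModel <- function(I0 = 1e5, noiseEnabled = FALSE) {
  new("PhotonModel", I0 = I0, noiseEnabled = noiseEnabled)
}

# ---- accessors -----------------------------------------------------------

#' @rdname ctGeometry
#' @param object,x a sparseCT object
#' @export
setGeneric("nAngles", function(object) standardGeneric("nAngles"))
#' @rdname ctGeometry
#' @export
setMethod("nAngles", "CTGeometry", function(object) object@nAngles)
#' @rdname ctGeometry
#' @export
setMethod("nAngles", "Sinogram", function(object) object@geometry@nAngles)

#' @rdname ctGeometry
#' @export
setGeneric("nDetectors", function(object) standardGeneric("nDetectors"))
#' @rdname ctGeometry
#' @export
setMethod("nDetectors", "CTGeometry", function(object) object@nDetectors)
#' @rdname ctGeometry
#' @export
setMethod("nDetectors", "Sinogram", function(object) object@geometry@nDetectors)

#' Projection angles of a geometry
#'
#' Uniform on the half-open interval [0, pi): angle j is (j-1)*pi/m2.
#' @param geometry a \linkS4class{CTGeometry}
#' @return numeric vector of length \code{nAngles(geometry)}
#' @export
projectionAngles <- function(geometry) {
  m2 <- geometry@nAngles
  (seq_len(m2) - 1) * pi / m2
}

#' Detector bin positions of a geometry (centred on the rotation axis)
#' @param geometry a \linkS4class{CTGeometry}
#' @return numeric vector of length \code{nDetectors(geometry)}
#' @export
detectorPositions <- function(geometry) {
  m1 <- geometry@nDetectors
  (seq_len(m1) - (m1 + 1) / 2) * geometry@detectorSpacing
}

#' Extract the pixel matrix of a CTImage
#' @param image a \linkS4class{CTImage}
#' @return numeric matrix
#' @export
imagePixels <- function(image) image@pixels

#' Extract the value matrix of a Sinogram
#' @param sino a \linkS4class{Sinogram}
#' @return numeric matrix m1 x m2
#' @export
sinogramValues <- function(sino) sino@values

#' Extract the geometry of a Sinogram
#' @param sino a \linkS4class{Sinogram}
#' @return a \linkS4class{CTGeometry}
#' @export
sinogramGeometry <- function(sino) sino@geometry

#' Extract the per-angle code of a ProjectionEncoding
#' @param encoding a \linkS4class{ProjectionEncoding}
#' @return numeric vector
#' @export
encodingValues <- function(encoding) encoding@e

#' Ellipse table of a PhantomSpec
#' @param spec a \linkS4class{PhantomSpec}
#' @return data.frame
#' @export
phantomEllipses <- function(spec) spec@ellipses

#' Number of parameters in a model component
#' @param object an EncoderParams, ProjReconParams, ImageReconParams or
#'   JointModel
#' @return integer count of scalar parameters
#' @export
setGeneric("paramCount", function(object) standardGeneric("paramCount"))

.countNumeric <- function(x) {
  if (is.list(x)) sum(vapply(x, .countNumeric, numeric(1))) else length(x)
}

#' @rdname paramCount
#' @export
setMethod("paramCount", "EncoderParams",
          function(object) .countNumeric(object@weights))
#' @rdname paramCount
#' @export
setMethod("paramCount", "ProjReconParams",
          function(object) .countNumeric(object@layers))
#' @rdname paramCount
#' @export
setMethod("paramCount", "ImageReconParams",
          function(object) .countNumeric(object@layers))
#' @rdname paramCount
#' @export
setMethod("paramCount", "JointModel", function(object)
  paramCount(object@encoder) + paramCount(object@projNet) +
    paramCount(object@imageNet))

# ---- show methods --------------------------------------------------------

setMethod("show", "CTGeometry", function(object) {
  cat(sprintf("CTGeometry: %d detectors (spacing %.4g), %d angles on [0, pi)\n",
              object@nDetectors, object@detectorSpacing, object@nAngles))
})

setMethod("show", "CTImage", function(object) {
  p <- object@pixels
  cat(sprintf("CTImage: %d x %d, values in [%.3g, %.3g], pixel size %.4g\n",
              nrow(p), ncol(p), min(p), max(p), object@pixelSize))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d detectors x %d angles, values in [%.3g, %.3g]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d ellipse(s)\n", nrow(object@ellipses)))
})

setMethod("show", "ProjectionEncoding", function(object) {
  e <- object@e
  cat(sprintf("ProjectionEncoding: %d angles, dose fraction %.4f, %d zero\n",
              length(e), mean(e), sum(e == 0)))
})

setMethod("show", "EncoderParams", function(object) {
  cat(sprintf("EncoderParams (G1): %d -> %d -> %d, lambda' = %.4g, %d params\n",
              object@dims$inputDim, object@dims$hidden, object@dims$m2,
              object@lambdaBias, paramCount(object)))
})

setMethod("show", "ProjReconParams", function(object) {
  cat(sprintf("ProjReconParams (G2'): 5 conv + 5 deconv, %d params\n",
              paramCount(object)))
})

setMethod("show", "ImageReconParams", function(object) {
  cat(sprintf("ImageReconParams (G2''): U-Net + 2x super-resolution head, %d params\n",
              paramCount(object)))
})

setMethod("show", "JointModel", function(object) {
  cat("JointModel (G1 o G2' o G2'')\n")
  show(object@encoder); show(object@projNet); show(object@imageNet)
  show(object@geometry)
})
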