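# Coupling of the three components: encode, apply the code, recover the
# sinogram, filtered back-projection, restore detail.

#' Full joint forward pass
#'
#' Runs the complete pipeline on a full-dose sinogram: the sampling code
#' from G1 (eval mode), the encoded sparse sinogram, its recovery by G2',
#' the FBP intermediate, and the final restored image from G2''. All
#' intermediates are returned for losses and visualisation.
#'
#' @param encoder an \linkS4class{EncoderParams}
#' @param projNet a \linkS4class{ProjReconParams}
#' @param imageNet an \linkS4class{ImageReconParams}
#' @param sino the full-dose \linkS4class{Sinogram}
#' @param n output image side; default inferred from the geometry
#' @return list with elements \code{encoding}, \code{encoded},
#'   \code{recovered} (Sinograms), \code{degraded} and \code{image}
#'   (CTImages)
#' @export
jointForward <- function(encoder, projNet, imageNet, sino, n = NULL) {
  stopifnot(is(sino, "Sinogram"))
  if (is.null(n)) n <- round(2 / sino@geometry@detectorSpacing)
  enc <- encodeProjections(encoder, sino, mode = "eval")
  mhat <- applyEncoding(sino, enc)
  mrec <- projReconForward(projNet, mhat)
  xdeg <- filteredBackprojection(mrec, n)
  xfin <- imageReconForward(imageNet, xdeg)
  list(encoding = enc, encoded = mhat, recovered = mrec,
       degraded = xdeg, image = xfin)
}

#' @rdname jointForward
#' @param model a \linkS4class{JointModel}
#' @export
jointReconstruct <- function(model, sino) {
  jointForward(model@encoder, model@projNet, model@imageNet, sino,
               n = model@config$n)
}

# End-to-end loss and gradient of mean((X_final - target)^2) with respect
# to all three parameter groups; eval-mode batch normalisation. Used by the
# gradient-connectivity checks.
.jointLossGrad <- function(encoder, projNet, imageNet, sino, target,
                           n = NULL) {
  g <- sino@geometry
  if (is.null(n)) n <- round(2 / g@detectorSpacing)
  M <- sino@values
  fe <- .encodeForward(encoder, list(M), mode = "eval")
  e <- fe$E[, 1]
  mhat <- sweep(M, 2, e, "*")
  pf <- .projFwd(projNet, mhat)
  fs <- .filterColumns(pf$out, g@detectorSpacing)
  xdeg <- cpp_backproject(fs, projectionAngles(g), detectorPositions(g)[1],
                          g@detectorSpacing, n, 2 / n, pi / g@nAngles)
  ifw <- .imgFwd(imageNet, xdeg)
  loss <- mean((ifw$out - target)^2)
  dxf <- 2 * (ifw$out - target) / length(target)
  ib <- .imgBwd(imageNet, ifw$cache, dxf)
  dmrec <- .fbpAdjoint(ib$dx, g, n)
  pb <- .projBwd(projNet, pf$cache, dmrec)
  dE <- matrix(colSums(pb$dx * M), ncol = 1)
  ge <- .encodeBackward(encoder, fe$cache, dE)
  list(loss = loss, encGrads = ge, projGrads = pb$grads,
       imageGrads = ib$grads)
}
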