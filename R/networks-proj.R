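# Sinogram-domain recovery network G2': five Conv+ReLU stages then five
# Deconv+ReLU stages, 64 channels, 3x3 kernels, stride 1, no padding, with
# a global residual connection (output = input + net(input)). The unpadded
# convolutions shrink each spatial dimension by 10; the deconvolutions
# restore it exactly. Because the full-dose sinogram dominates its encoded
# version entrywise, the residual the network must express is non-negative,
# so the terminal ReLU costs no generality.

.projArch <- function() {
  a <- list(.meta("conv", 1L, 64L, 3L))
  for (i in 2:5) a[[i]] <- .meta("conv", 64L, 64L, 3L)
  for (i in 6:9) a[[i]] <- .meta("deconv", 64L, 64L, 3L)
  a[[10]] <- .meta("deconv", 64L, 1L, 3L)
  a
}

#' Initialise the sinogram-recovery network G2'
#'
#' @param seed initialisation seed (He-uniform weights)
#' @return a \linkS4class{ProjReconParams}
#' @export
newProjReconParams <- function(seed = 0L) {
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  arch <- .projArch()
  new("ProjReconParams", layers = lapply(arch, .initLayer),
      seed = as.integer(seed))
}

.projMinSize <- 11L

.projFwd <- function(params, x, wantCache = TRUE) {
  if (nrow(x) < .projMinSize || ncol(x) < .projMinSize)
    stop(sprintf(
      "sinogram must be at least %d x %d (five unpadded 3x3 convolutions)",
      .projMinSize, .projMinSize))
  arch <- .projArch()
  h <- array(x, c(nrow(x), ncol(x), 1L))
  ins <- vector("list", 10L); masks <- vector("list", 10L)
  for (l in 1:10) {
    if (wantCache) ins[[l]] <- h
    h <- .layF(arch[[l]], params@layers[[l]], h)
    m <- h > 0
    h <- h * m
    if (wantCache) masks[[l]] <- m
  }
  out <- x + h[, , 1L]
  list(out = out, cache = if (wantCache) list(ins = ins, masks = masks))
}

.projBwd <- function(params, cache, dout) {
  arch <- .projArch()
  grads <- vector("list", 10L)
  dh <- array(dout, c(nrow(dout), ncol(dout), 1L))
  for (l in 10:1) {
    dh <- dh * cache$masks[[l]]
    r <- .layB(arch[[l]], params@layers[[l]], cache$ins[[l]], dh)
    grads[[l]] <- list(W = r$dW, b = as.numeric(r$db))
    dh <- r$dx
  }
  list(grads = grads, dx = dout + dh[, , 1L])
}

#' Recover a full sinogram from a sparsely encoded one
#'
#' Forward pass of the residual network G2': output = input + net(input),
#' preserving the sinogram shape.
#'
#' @param params a \linkS4class{ProjReconParams}
#' @param sino a \linkS4class{Sinogram} (both dimensions >= 11)
#' @return a \linkS4class{Sinogram} of the same shape
#' @export
projReconForward <- function(params, sino) {
  stopifnot(is(params, "ProjReconParams"), is(sino, "Sinogram"))
  r <- .projFwd(params, sino@values, wantCache = FALSE)
  sinogram(r$out, sino@geometry)
}
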