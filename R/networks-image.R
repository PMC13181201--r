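# Image-domain detail-restoration network G2'' — a U-Net style
# encoder/decoder with three 3-stage skip paths, a 1-channel bridging
# convolution at half resolution, and a 2x back-projection
# super-resolution head.
#
# Encoder: conv module (two 3x3 convs, width 32) + four 2x downsampling
# modules (maxpool + two convs, widths 64/128/256/512). Decoder: three 2x
# upsampling modules (bilinear interpolation + two convs) fusing the
# encoder features at 1/2, 1/4 and 1/8 scale by channel concatenation,
# then the bridge and the super-resolution head back to full resolution.
# Decoder/encoder convs use padding 1 so the skip shapes align; the
# unpadded-convolution convention is kept only in the sinogram network
# whose deconvolution stack restores size.

.imageArch <- function() {
  list(
    e0a = .meta("conv", 1L, 32L, 3L, pad = 1L),
    e0b = .meta("conv", 32L, 32L, 3L, pad = 1L),
    d1a = .meta("conv", 32L, 64L, 3L, pad = 1L),
    d1b = .meta("conv", 64L, 64L, 3L, pad = 1L),
    d2a = .meta("conv", 64L, 128L, 3L, pad = 1L),
    d2b = .meta("conv", 128L, 128L, 3L, pad = 1L),
    d3a = .meta("conv", 128L, 256L, 3L, pad = 1L),
    d3b = .meta("conv", 256L, 256L, 3L, pad = 1L),
    d4a = .meta("conv", 256L, 512L, 3L, pad = 1L),
    d4b = .meta("conv", 512L, 512L, 3L, pad = 1L),
    s1a = .meta("conv", 64L, 64L, 3L, pad = 1L),
    s1b = .meta("conv", 64L, 64L, 3L, pad = 1L),
    s1c = .meta("conv", 64L, 64L, 3L, pad = 1L),
    s2a = .meta("conv", 128L, 128L, 3L, pad = 1L),
    s2b = .meta("conv", 128L, 128L, 3L, pad = 1L),
    s2c = .meta("conv", 128L, 128L, 3L, pad = 1L),
    s3a = .meta("conv", 256L, 256L, 3L, pad = 1L),
    s3b = .meta("conv", 256L, 256L, 3L, pad = 1L),
    s3c = .meta("conv", 256L, 256L, 3L, pad = 1L),
    u1a = .meta("conv", 768L, 256L, 3L, pad = 1L),
    u1b = .meta("conv", 256L, 256L, 3L, pad = 1L),
    u2a = .meta("conv", 384L, 128L, 3L, pad = 1L),
    u2b = .meta("conv", 128L, 128L, 3L, pad = 1L),
    u3a = .meta("conv", 192L, 64L, 3L, pad = 1L),
    u3b = .meta("conv", 64L, 64L, 3L, pad = 1L),
    bridge = .meta("conv", 64L, 1L, 3L, pad = 1L),
    # super-resolution head: T = 2 projection pairs, 32 features,
    # 6/2/2 kernels for the exact 2x scale
    pf = .meta("conv", 1L, 32L, 3L, pad = 1L, act = "prelu"),
    up1d = .meta("deconv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    up1c = .meta("conv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    up1e = .meta("deconv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    dn1c = .meta("conv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    dn1d = .meta("deconv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    dn1e = .meta("conv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    up2d = .meta("deconv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    up2c = .meta("conv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    up2e = .meta("deconv", 32L, 32L, 6L, stride = 2L, pad = 2L, act = "prelu"),
    # zero-initialised so the residual network starts at the identity
    rec = .meta("conv", 64L, 1L, 3L, pad = 1L, init = "zero")
  )
}

#' Initialise the image detail-restoration network G2''
#'
#' @param seed initialisation seed (He-uniform weights)
#' @return an \linkS4class{ImageReconParams}
#' @export
newImageReconParams <- function(seed = 0L) {
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  arch <- .imageArch()
  new("ImageReconParams", layers = lapply(arch, .initLayer),
      seed = as.integer(seed))
}

# forward helpers bound to a cache environment
.mkOps <- function(params, arch, cc) {
  w <- params@layers
  cr <- function(name, x) {            # conv/deconv + ReLU or PReLU
    y <- .layF(arch[[name]], w[[name]], x)
    assign(paste0(name, ".in"), x, envir = cc)
    if (identical(arch[[name]]$act, "prelu")) {
      assign(paste0(name, ".pre"), y, envir = cc)
      pos <- y > 0
      y * pos + w[[name]]$a * y * (!pos)
    } else {
      m <- y > 0
      assign(paste0(name, ".mask"), m, envir = cc)
      y * m
    }
  }
  cl <- function(name, x) {            # linear conv
    assign(paste0(name, ".in"), x, envir = cc)
    .layF(arch[[name]], w[[name]], x)
  }
  pl <- function(name, x) {
    r <- cpp_maxpool2(x)
    assign(paste0(name, ".amax"), r$amax, envir = cc)
    assign(paste0(name, ".dim"), dim(x), envir = cc)
    r$y
  }
  up <- function(name, x) {
    assign(paste0(name, ".dim"), dim(x), envir = cc)
    cpp_upsample2(x)
  }
  list(cr = cr, cl = cl, pl = pl, up = up)
}

.mkBwd <- function(params, arch, cc, grads) {
  w <- params@layers
  crB <- function(name, dy) {
    if (identical(arch[[name]]$act, "prelu")) {
      pre <- get(paste0(name, ".pre"), envir = cc)
      neg <- pre <= 0
      da <- sum(dy * pre * neg)
      dy <- dy * (!neg) + w[[name]]$a * dy * neg
      g <- grads[[name]]
      r <- .layB(arch[[name]], w[[name]],
                 get(paste0(name, ".in"), envir = cc), dy)
      grads[[name]] <<- list(W = g$W + r$dW, b = g$b + as.numeric(r$db),
                             a = g$a + da)
    } else {
      dy <- dy * get(paste0(name, ".mask"), envir = cc)
      r <- .layB(arch[[name]], w[[name]],
                 get(paste0(name, ".in"), envir = cc), dy)
      grads[[name]] <<- list(W = grads[[name]]$W + r$dW,
                             b = grads[[name]]$b + as.numeric(r$db))
    }
    r$dx
  }
  clB <- function(name, dy) {
    r <- .layB(arch[[name]], w[[name]], get(paste0(name, ".in"), envir = cc), dy)
    grads[[name]] <<- list(W = grads[[name]]$W + r$dW,
                           b = grads[[name]]$b + as.numeric(r$db))
    r$dx
  }
  plB <- function(name, dy) {
    d <- get(paste0(name, ".dim"), envir = cc)
    cpp_maxpool2_bwd(get(paste0(name, ".amax"), envir = cc), dy, d[1], d[2])
  }
  upB <- function(name, dy) {
    d <- get(paste0(name, ".dim"), envir = cc)
    cpp_upsample2_bwd(dy, d[1], d[2])
  }
  environment()
}

# DBPN chain: input br (h, w, 1), output (2h, 2w, 1). The projection units
# compute iterative residual corrections between the two scales; the two
# high-resolution feature maps are concatenated for the reconstruction
# convolution.
.dbpnChain <- function(ops, br, cc) {
  cr <- ops$cr; cl <- ops$cl
  Ld <- cr("pf", br)
  H0 <- cr("up1d", Ld)
  L0 <- cr("up1c", H0)
  H1 <- cr("up1e", L0 - Ld) + H0
  L1 <- cr("dn1c", H1)
  H1b <- cr("dn1d", L1)
  L2 <- cr("dn1e", H1b - H1) + L1
  H0b <- cr("up2d", L2)
  L0b <- cr("up2c", H0b)
  H2 <- cr("up2e", L0b - L2) + H0b
  assign("dbpn.H1", H1, envir = cc)  # reused by the backward split
  cl("rec", .cat3(H1, H2))
}

.dbpnChainBwd <- function(bw, dy) {
  crB <- bw$crB; clB <- bw$clB
  dcat <- clB("rec", dy)
  dH1 <- .slice3(dcat, 1, 32)
  dH2 <- .slice3(dcat, 33, 64)
  # H2 = relu(up2e(L0b - L2)) + H0b
  dE3 <- crB("up2e", dH2)
  dH0b <- dH2
  dL0b <- dE3
  dL2 <- -dE3
  dH0b <- dH0b + crB("up2c", dL0b)
  dL2 <- dL2 + crB("up2d", dH0b)
  # L2 = relu(dn1e(H1b - H1)) + L1
  dE2 <- crB("dn1e", dL2)
  dL1 <- dL2
  dH1b <- dE2
  dH1 <- dH1 - dE2
  dL1 <- dL1 + crB("dn1d", dH1b)
  dH1 <- dH1 + crB("dn1c", dL1)
  # H1 = relu(up1e(L0 - Ld)) + H0
  dE1 <- crB("up1e", dH1)
  dH0 <- dH1
  dL0 <- dE1
  dLd <- -dE1
  dH0 <- dH0 + crB("up1c", dL0)
  dLd <- dLd + crB("up1d", dH0)
  crB("pf", dLd)
}

.imgFwd <- function(params, x) {
  n <- nrow(x)
  if (n %% 16 != 0)
    stop("image side must be divisible by 16 (four 2x downsampling stages ",
         "plus the 2x super-resolution head)")
  arch <- .imageArch()
  cc <- new.env(parent = emptyenv())
  ops <- .mkOps(params, arch, cc)
  cr <- ops$cr; cl <- ops$cl; pl <- ops$pl; up <- ops$up
  xx <- array(x, c(n, n, 1L))
  f0 <- cr("e0b", cr("e0a", xx))
  f1 <- cr("d1b", cr("d1a", pl("p1", f0)))
  f2 <- cr("d2b", cr("d2a", pl("p2", f1)))
  f3 <- cr("d3b", cr("d3a", pl("p3", f2)))
  f4 <- cr("d4b", cr("d4a", pl("p4", f3)))
  k3 <- cr("s3c", cr("s3b", cr("s3a", f3)))
  k2 <- cr("s2c", cr("s2b", cr("s2a", f2)))
  k1 <- cr("s1c", cr("s1b", cr("s1a", f1)))
  u1 <- cr("u1b", cr("u1a", .cat3(up("upA", f4), k3)))
  u2 <- cr("u2b", cr("u2a", .cat3(up("upB", u1), k2)))
  u3 <- cr("u3b", cr("u3a", .cat3(up("upC", u2), k1)))
  br <- cl("bridge", u3)
  y <- .dbpnChain(ops, br, cc)
  # global residual: degradation superposes on the reconstruction (FBP is
  # linear), so the network learns the additive artifact, not the image
  list(out = x + y[, , 1L], cache = cc)
}

.imgBwd <- function(params, cache, dout) {
  arch <- .imageArch()
  grads <- .tzero(params@layers)
  bw <- .mkBwd(params, arch, cache, grads)
  dy <- array(dout, c(nrow(dout), ncol(dout), 1L))
  dbr <- .dbpnChainBwd(bw, dy)
  crB <- bw$crB; clB <- bw$clB; plB <- bw$plB; upB <- bw$upB
  du3 <- clB("bridge", dbr)
  dcat <- crB("u3a", crB("u3b", du3))
  du2 <- upB("upC", .slice3(dcat, 1, 128))
  dk1 <- .slice3(dcat, 129, 192)
  dcat <- crB("u2a", crB("u2b", du2))
  du1 <- upB("upB", .slice3(dcat, 1, 256))
  dk2 <- .slice3(dcat, 257, 384)
  dcat <- crB("u1a", crB("u1b", du1))
  df4 <- upB("upA", .slice3(dcat, 1, 512))
  dk3 <- .slice3(dcat, 513, 768)
  df1 <- crB("s1a", crB("s1b", crB("s1c", dk1)))
  df2 <- crB("s2a", crB("s2b", crB("s2c", dk2)))
  df3 <- crB("s3a", crB("s3b", crB("s3c", dk3)))
  df3 <- df3 + plB("p4", crB("d4a", crB("d4b", df4)))
  df2 <- df2 + plB("p3", crB("d3a", crB("d3b", df3)))
  df1 <- df1 + plB("p2", crB("d2a", crB("d2b", df2)))
  df0 <- plB("p1", crB("d1a", crB("d1b", df1)))
  dx <- crB("e0a", crB("e0b", df0))
  list(grads = bw$grads, dx = dout + dx[, , 1L])
}

#' Restore image detail from a degraded reconstruction
#'
#' Forward pass of the U-Net style restoration network G2'':
#' output = input + net(input). The global residual follows from the
#' superposition of the degradation: FBP is linear, so the artifact the
#' network must remove is additive on the reconstruction. The input side
#' length must be divisible by 16 (four downsampling stages and the final
#' 2x super-resolution); the output has the input's shape.
#'
#' @param params an \linkS4class{ImageReconParams}
#' @param image a \linkS4class{CTImage}
#' @return a \linkS4class{CTImage}
#' @export
imageReconForward <- function(params, image) {
  stopifnot(is(params, "ImageReconParams"), is(image, "CTImage"))
  r <- .imgFwd(params, image@pixels)
  ctImage(r$out, image@pixelSize)
}

#' 2x super-resolution head (back-projection network)
#'
#' Runs only the super-resolution head of the restoration network on a
#' 1-channel low-resolution image: alternating up-/down-projection units
#' (kernel 6, stride 2, padding 2) computing iterative residual
#' corrections, then a reconstruction convolution back to 1 channel. The
#' output has exactly twice the spatial dimensions.
#'
#' @param params an \linkS4class{ImageReconParams} (holds the head weights)
#' @param lowres numeric matrix, or an (h, w, 1) array
#' @return numeric matrix of dimensions (2h, 2w)
#' @export
dbpnForward <- function(params, lowres) {
  stopifnot(is(params, "ImageReconParams"))
  if (length(dim(lowres)) == 3L) {
    if (dim(lowres)[3] != 1L)
      stop("the super-resolution head takes a single-channel input")
    lowres <- lowres[, , 1L]
  }
  arch <- .imageArch()
  cc <- new.env(parent = emptyenv())
  ops <- .mkOps(params, arch, cc)
  br <- array(lowres, c(nrow(lowres), ncol(lowres), 1L))
  .dbpnChain(ops, br, cc)[, , 1L]
}
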