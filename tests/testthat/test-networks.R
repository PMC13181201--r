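test_that("sinogram-recovery network is the exact identity at zero weights", {
  pr <- zeroedParams(newProjReconParams(seed = 1))
  g <- ctGeometry(23, 12, 0.1)
  set.seed(2)
  x <- matrix(runif(23 * 12), 23, 12)
  out <- projReconForward(pr, sinogram(x, g))
  expect_identical(sinogramValues(out), x)
})

test_that("both networks preserve shape across the supported sizes", {
  pr <- newProjReconParams(seed = 1)
  ir <- newImageReconParams(seed = 2)
  for (n in c(32L, 48L, 64L, 96L, 128L)) {
    x <- matrix(runif(n * n), n, n)
    yp <- sparseCT:::.projFwd(pr, x, wantCache = FALSE)$out
    expect_identical(dim(yp), c(n, n))
    yi <- sparseCT:::.imgFwd(ir, x)$out
    expect_identical(dim(yi), c(n, n))
  }
  # non-square sinograms are fine for the recovery net
  x <- matrix(runif(91 * 60), 91, 60)
  expect_identical(dim(sparseCT:::.projFwd(pr, x, wantCache = FALSE)$out),
                   c(91L, 60L))
})

test_that("size preconditions are enforced with informative errors", {
  pr <- newProjReconParams(seed = 1)
  ir <- newImageReconParams(seed = 2)
  expect_error(sparseCT:::.projFwd(pr, matrix(0, 10, 20)), "at least 11")
  expect_error(sparseCT:::.imgFwd(ir, matrix(0, 50, 50)),
               "divisible by 16")
  expect_error(imageReconForward(ir, ctImage(matrix(0, 40, 40))),
               "divisible by 16")
})

test_that("the super-resolution head doubles 1-channel images exactly", {
  ir <- newImageReconParams(seed = 3)
  x <- matrix(runif(32 * 32), 32)
  y <- dbpnForward(ir, x)
  expect_identical(dim(y), c(64L, 64L))
  y2 <- dbpnForward(ir, x)
  expect_identical(y, y2)                  # deterministic
  expect_error(dbpnForward(ir, array(0, c(16, 16, 2))), "single-channel")
})

test_that("construction is deterministic in seed and architecture", {
  a <- newImageReconParams(seed = 9)
  b <- newImageReconParams(seed = 9)
  expect_identical(a@layers, b@layers)
  expect_identical(paramCount(a), paramCount(b))
  expect_false(identical(a@layers,
                         newImageReconParams(seed = 10)@layers))
  p1 <- newProjReconParams(seed = 4)
  set.seed(99)
  x <- matrix(runif(23 * 12), 23, 12)
  g <- ctGeometry(23, 12, 0.1)
  expect_identical(sinogramValues(projReconForward(p1, sinogram(x, g))),
                   sinogramValues(projReconForward(p1, sinogram(x, g))))
})

test_that("backward passes agree with central finite differences", {
  set.seed(31)
  pr <- newProjReconParams(seed = 1)
  x <- matrix(runif(23 * 12), 23, 12)
  tgt <- matrix(runif(23 * 12), 23, 12)
  pf <- sparseCT:::.projFwd(pr, x)
  pb <- sparseCT:::.projBwd(pr, pf$cache, 2 * (pf$out - tgt) / length(tgt))
  lossP <- function(p) {
    o <- sparseCT:::.projFwd(p, x, wantCache = FALSE)$out
    mean((o - tgt)^2)
  }
  h <- 1e-6
  for (l in c(1L, 5L, 10L)) {
    idx <- sample(length(pr@layers[[l]]$W), 2)
    for (i in idx) {
      pp <- pr; pp@layers[[l]]$W[i] <- pp@layers[[l]]$W[i] + h
      pm <- pr; pm@layers[[l]]$W[i] <- pm@layers[[l]]$W[i] - h
      fd <- (lossP(pp) - lossP(pm)) / (2 * h)
      expect_equal(pb$grads[[l]]$W[i], fd, tolerance = 1e-4)
    }
  }
  ir <- newImageReconParams(seed = 2)
  # the reconstruction layer is zero-initialised (identity start); move it
  # off zero so gradients flow to every upstream layer being checked
  ir@layers$rec$W[] <- runif(length(ir@layers$rec$W), -0.05, 0.05)
  x2 <- matrix(runif(16 * 16), 16)
  t2 <- matrix(runif(16 * 16), 16)
  fw <- sparseCT:::.imgFwd(ir, x2)
  ib <- sparseCT:::.imgBwd(ir, fw$cache, 2 * (fw$out - t2) / length(t2))
  lossI <- function(p) {
    o <- sparseCT:::.imgFwd(p, x2)$out
    mean((o - t2)^2)
  }
  for (nm in c("e0a", "d4b", "s2b", "u1a", "bridge", "dn1d", "rec")) {
    i <- sample(length(ir@layers[[nm]]$W), 1)
    pp <- ir; pp@layers[[nm]]$W[i] <- pp@layers[[nm]]$W[i] + h
    pm <- ir; pm@layers[[nm]]$W[i] <- pm@layers[[nm]]$W[i] - h
    fd <- (lossI(pp) - lossI(pm)) / (2 * h)
    expect_equal(ib$grads[[nm]]$W[i], fd,
                 tolerance = 1e-3 * max(1, abs(fd)))
  }
})

test_that("joint forward composes the stages and returns intermediates", {
  tc <- tinyCase()
  m2 <- nAngles(tc$geom)
  enc <- newEncoderParams(tc$geom, hidden = 8L, seed = 1)
  # drive the code to all-ones: a large BN shift saturates the clamp
  enc@weights$beta <- rep(10, m2)
  pr0 <- zeroedParams(newProjReconParams(seed = 1))
  ir <- newImageReconParams(seed = 2)
  jf <- jointForward(enc, pr0, ir, tc$sino)
  expect_true(all(encodingValues(jf$encoding) == 1))
  # all-ones code + zero-weight recovery net: the FBP intermediate is
  # exactly fbp(radon(X))
  ref <- filteredBackprojection(tc$sino, 16)
  expect_identical(imagePixels(jf$degraded), imagePixels(ref))
  expect_identical(dim(imagePixels(jf$image)),
                   dim(imagePixels(tc$phantom$image)))
  expect_identical(dim(sinogramValues(jf$recovered)),
                   dim(sinogramValues(tc$sino)))
})

test_that("an image loss reaches all three parameter groups end-to-end", {
  tc <- tinyCase()
  enc <- newEncoderParams(tc$geom, hidden = 16L, seed = 5)
  ds <- phantomDataset(6, 16, c(2, 5), seed = 9)
  sinos <- lapply(ds, function(it) radonTransform(it$image, tc$geom))
  cal <- calibrateLambda(enc, sinos, 0.4)
  enc@lambdaBias <- cal$lambda
  enc@bnState <- cal$bnState
  pr <- newProjReconParams(seed = 1)
  ir <- newImageReconParams(seed = 2)
  set.seed(41)
  ir@layers$rec$W[] <- runif(length(ir@layers$rec$W), -0.05, 0.05)
  tgt <- imagePixels(tc$phantom$image)
  jl <- sparseCT:::.jointLossGrad(enc, pr, ir, tc$sino, tgt)
  expect_gt(sum(abs(jl$encGrads$W1)), 0)
  expect_gt(sum(abs(jl$projGrads[[1]]$W)), 0)
  expect_gt(sum(abs(jl$imageGrads$e0a$W)), 0)
  # finite-difference agreement on encoder weights (1e-3 relative)
  h <- 1e-5
  lossOf <- function(ee)
    sparseCT:::.jointLossGrad(ee, pr, ir, tc$sino, tgt)$loss
  set.seed(8)
  checked <- 0L
  for (i in sample(length(enc@weights$W1), 12)) {
    an <- jl$encGrads$W1[i]
    if (abs(an) < 1e-8) next
    pp <- enc; pp@weights$W1[i] <- pp@weights$W1[i] + h
    pm <- enc; pm@weights$W1[i] <- pm@weights$W1[i] - h
    fd <- (lossOf(pp) - lossOf(pm)) / (2 * h)
    expect_lt(abs(an - fd) / max(abs(an), abs(fd)), 1e-3)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})
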