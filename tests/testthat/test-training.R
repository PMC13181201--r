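test_that("losses vanish exactly at their minima and stay non-negative", {
  tc <- tinyCase()
  M <- sinogramValues(tc$sino)
  m2 <- nAngles(tc$geom)
  eAt <- function(d) projectionEncoding(rep(d, m2))
  expect_equal(lossProjection(M, M, eAt(0.4), 0.4), 0)
  expect_equal(lossProjection(M, M, eAt(0.5), 0.4, 1), 0.1,
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    a <- matrix(runif(12), 4, 3); b <- matrix(runif(12), 4, 3)
    expect_gte(lossProjection(a, b, projectionEncoding(runif(m2)), 0.3), 0)
    expect_gte(lossImage(a, b), 0)
    expect_equal(lossImage(a, b), lossImage(b, a))
  }
  x <- matrix(0.5, 8, 8)
  expect_identical(lossImage(x, x), 0)
  expect_equal(lossImage(x, x + 0.1), 0.01, tolerance = 1e-15)
  expect_error(lossImage(x, matrix(0, 4, 4)), "shape")
})

test_that("bias calibration hits the dose target and is self-consistent", {
  g <- defaultGeometry(16, 12)
  ds <- phantomDataset(16, 16, c(2, 6), seed = 4)
  sinos <- lapply(ds, function(it) radonTransform(it$image, g))
  enc <- newEncoderParams(g, hidden = 16L, seed = 2)
  for (gam in c(0.2, 0.3, 0.4)) {
    cal <- calibrateLambda(enc, sinos, gam)
    expect_lt(abs(cal$achievedDose - gam), 0.01)
    # re-evaluating the batch at the returned bias reproduces the dose
    enc2 <- enc
    enc2@lambdaBias <- cal$lambda
    fw <- sparseCT:::.encodeForward(
      enc2, lapply(sinos, sinogramValues), "train")
    expect_equal(mean(colMeans(fw$E)), cal$achievedDose, tolerance = 1e-12)
    # determinism
    expect_identical(calibrateLambda(enc, sinos, gam)$lambda, cal$lambda)
  }
  # a saturated-at-1 code returns the lower bracket edge
  encHi <- enc
  encHi@weights$beta <- rep(50, 12)
  calHi <- calibrateLambda(encHi, sinos, 1)
  expect_identical(calHi$lambda, 0)
  expect_error(calibrateLambda(enc, sinos, 0.999), "unreachable")
})

# a two-copy micro dataset: Step-2/Step-3 smoke runs that overfit a single
# phantom (the held-out item is a copy of the training item)
.microConfig <- function(epochs2 = 1L, epochs3 = 1L, seed = 5L) {
  trainingConfig(n = 32L, nAngles = 24L, gamma = 0.4, lr = 1e-3,
                 epochsStep2 = epochs2, epochsStep3 = epochs3,
                 batchSize = 2L, batchSizeStep3 = 1L, count = 3L,
                 kRange = c(3L, 5L), evalSubset = 1L, seed = seed)
}

.microDataset <- function(seed = 5L) {
  one <- randomPhantom(32, 4, seed)
  list(one, one, one)
}

test_that("step 2 overfits a single phantom and respects the dose band", {
  cfg <- .microConfig(epochs2 = 25L)
  s2 <- fixtureOnce("microStep2", trainStep2(cfg, .microDataset()))
  h <- s2$history
  expect_lt(h$loss[nrow(h)], 0.1 * h$loss[1])
  expect_lt(h$doseDiff[nrow(h)], 0.05)
  expect_true(all(is.finite(unlist(h))))
  expect_identical(nrow(h), 25L)
})

test_that("step 2 histories are bit-identical under a fixed seed", {
  cfg <- .microConfig(epochs2 = 2L)
  a <- trainStep2(cfg, .microDataset())
  b <- trainStep2(cfg, .microDataset())
  expect_identical(a$history, b$history)
  expect_identical(a$encoder@weights, b$encoder@weights)
  expect_identical(a$projNet@layers, b$projNet@layers)
})

test_that("step 3 overfits, improves SSIM, and never touches step-2
           parameters", {
  cfg <- .microConfig(epochs2 = 25L, epochs3 = 40L)
  s2 <- fixtureOnce("microStep2", trainStep2(cfg, .microDataset()))
  encBefore <- s2$encoder@weights
  prBefore <- s2$projNet@layers
  s3 <- fixtureOnce("microStep3", trainStep3(cfg, s2))
  h <- s3$history
  # the restoration network starts at the identity (global residual +
  # zero-initialised head), so the initial loss is already the FBP
  # artifact level rather than a random-init loss; the overfit threshold
  # is frozen from this implementation's reference run
  expect_lt(h$loss[nrow(h)], 0.95 * h$loss[1])
  expect_gt(h$ssim[nrow(h)], h$ssim[1])
  expect_identical(s2$encoder@weights, encBefore)   # freeze contract
  expect_identical(s2$projNet@layers, prBefore)
})

test_that("the joint run produces a loadable checkpoint and full report", {
  cfg <- .microConfig(epochs2 = 2L, epochs3 = 2L)
  run <- fixtureOnce("microJoint", runJointTraining(cfg, .microDataset()))
  expect_s4_class(run$model, "JointModel")
  expect_named(run$report,
               c("ssim", "psnr", "mse", "doseFraction", "doseDifference",
                 "nHoldout"), ignore.order = TRUE)
  expect_true(all(is.finite(unlist(run$report[c("ssim", "psnr", "mse")]))))
  p <- tempfile(fileext = ".rds")
  saveCheckpoint(run$model, p)
  model <- loadCheckpoint(p)
  jf <- jointReconstruct(model, radonTransform(.microDataset()[[1]]$image,
                                               run$model@geometry))
  expect_identical(dim(imagePixels(jf$image)), c(32L, 32L))
  # end-to-end reproducibility
  run2 <- runJointTraining(cfg, .microDataset())
  expect_identical(run$historyStep2, run2$historyStep2)
  expect_identical(run$historyStep3, run2$historyStep3)
  expect_identical(run$report, run2$report)
})

test_that("the ablation table has three arms and the comparison two", {
  cfg <- .microConfig(epochs2 = 2L, epochs3 = 2L)
  ab <- runAblation(cfg, .microDataset())
  expect_identical(nrow(ab$table), 3L)
  expect_setequal(ab$table$arm, c("G1.G2p.G2pp", "G1.G2p", "G1.G2pp"))
  expect_true(all(is.finite(ab$table$ssim)))
  cs <- compareSampling(cfg, .microDataset())
  expect_identical(nrow(cs$table), 2L)
  # matched to the nearest representable equal-interval dose
  expect_lte(abs(cs$table$doseFraction[1] - cs$table$doseFraction[2]),
             1 / (2 * cfg$nAngles) + 1e-12)
})
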