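test_that("biased ReLU thresholds as specified", {
  expect_equal(biasedReLU(0.5, 0.2), 0.3)
  expect_equal(biasedReLU(-1.0, 0), 0)
  expect_equal(biasedReLU(0.2, 0.5), 0)
  expect_error(biasedReLU(1, -0.1), "lambdaBias")
})

test_that("dose fraction is the normalised L1 measure", {
  expect_identical(doseFraction(projectionEncoding(rep(1, 90))), 1)
  expect_identical(doseFraction(projectionEncoding(rep(0, 90))), 0)
  expect_equal(doseFraction(projectionEncoding(
    rep(c(1, 0, 0), 30))), 1 / 3)
})

test_that("applying a code scales sinogram columns", {
  tc <- tinyCase()
  m2 <- nAngles(tc$geom)
  ones <- projectionEncoding(rep(1, m2))
  expect_identical(sinogramValues(applyEncoding(tc$sino, ones)),
                   sinogramValues(tc$sino))
  zero <- projectionEncoding(rep(0, m2))
  expect_true(all(sinogramValues(applyEncoding(tc$sino, zero)) == 0))
  e <- rep(1, m2); e[3] <- 0.5
  got <- sinogramValues(applyEncoding(tc$sino, projectionEncoding(e)))
  ref <- sinogramValues(tc$sino)
  expect_identical(got[, 3], 0.5 * ref[, 3])
  expect_identical(got[, -3], ref[, -3])
  expect_error(applyEncoding(tc$sino, projectionEncoding(rep(1, m2 + 1))),
               "length")
})

test_that("equal-interval sampling places angles as documented", {
  e <- encodingValues(equalIntervalEncoding(90, 1 / 3))
  expect_identical(which(e == 1), seq(1L, 88L, by = 3L))
  expect_equal(doseFraction(projectionEncoding(e)), 1 / 3)
  expect_true(all(encodingValues(equalIntervalEncoding(90, 1)) == 1))
  e10 <- encodingValues(equalIntervalEncoding(10, 0.25))
  expect_identical(which(e10 == 1), c(1L, 6L))    # k = 2, indices 0 and 5
  expect_error(equalIntervalEncoding(10, 0.01), "zero")
})

test_that("the encoder produces bounded codes deterministically", {
  tc <- tinyCase()
  enc <- newEncoderParams(tc$geom, hidden = 16L, seed = 5,
                          lambdaBias = 0.3)
  e1 <- encodeProjections(enc, tc$sino, "eval")
  e2 <- encodeProjections(enc, tc$sino, "eval")
  expect_identical(encodingValues(e1), encodingValues(e2))
  expect_length(encodingValues(e1), nAngles(tc$geom))
  expect_true(all(encodingValues(e1) >= 0 & encodingValues(e1) <= 1))
  # a bias above every activation silences the code entirely
  encHi <- enc
  encHi@lambdaBias <- 1e6
  expect_true(all(encodingValues(
    encodeProjections(encHi, tc$sino, "eval")) == 0))
  expect_error(encodeProjections(enc, sinogram(
    matrix(0, 23, 13), ctGeometry(23, 13, 0.1)), "eval"), "shape")
})

test_that("sparsity is monotone in the bias over a lambda sweep", {
  tc <- tinyCase()
  enc <- newEncoderParams(tc$geom, hidden = 16L, seed = 6)
  lams <- seq(0, 3, length.out = 20)
  res <- vapply(lams, function(l) {
    enc@lambdaBias <- l
    e <- encodingValues(encodeProjections(enc, tc$sino, "eval"))
    c(l1 = sum(e), zeros = sum(e == 0))
  }, numeric(2))
  expect_true(all(diff(res["l1", ]) <= 1e-12))
  expect_true(all(diff(res["zeros", ]) >= 0))
})

test_that("the dose penalty propagates to the FCN weights", {
  tc <- tinyCase()
  enc <- newEncoderParams(tc$geom, hidden = 8L, seed = 7,
                          lambdaBias = 0.2)
  gamma <- 0.3
  # analytic gradient of |dose - gamma| through the encoder (eval mode)
  fw <- sparseCT:::.encodeForward(enc, list(sinogramValues(tc$sino)),
                                  "eval")
  m2 <- nAngles(tc$geom)
  ds <- sum(fw$E[, 1]) / m2
  dE <- matrix(sign(ds - gamma) / m2, m2, 1)
  gr <- sparseCT:::.encodeBackward(enc, fw$cache, dE)
  expect_gt(sum(abs(gr$W1)), 0)
  lossOf <- function(p) {
    e <- sparseCT:::.encodeForward(p, list(sinogramValues(tc$sino)),
                                   "eval")$E[, 1]
    abs(sum(e) / m2 - gamma)
  }
  h <- 1e-6
  set.seed(1)
  checked <- 0L
  for (i in sample(length(enc@weights$W1), 20)) {
    if (abs(gr$W1[i]) < 1e-9) next
    p1 <- enc; p1@weights$W1[i] <- p1@weights$W1[i] + h
    p2 <- enc; p2@weights$W1[i] <- p2@weights$W1[i] - h
    fd <- (lossOf(p1) - lossOf(p2)) / (2 * h)
    expect_equal(gr$W1[i], fd, tolerance = 1e-4)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("exported fixed schemes average codes and binarise to top-k", {
  tc <- tinyCase()
  enc <- newEncoderParams(tc$geom, hidden = 16L, seed = 8,
                          lambdaBias = 0.4)
  # identical inputs -> the common code
  same <- list(tc$sino, tc$sino, tc$sino)
  fixed <- exportFixedEncoding(enc, same)
  expect_equal(encodingValues(fixed),
               encodingValues(encodeProjections(enc, tc$sino, "eval")),
               tolerance = 1e-12)
  # binarised scheme has exactly round(m2 * gamma) kept angles
  other <- tinyCase(seed = 11)
  mixed <- list(tc$sino, other$sino)
  bin <- exportFixedEncoding(enc, mixed, binarize = TRUE, gamma = 0.25)
  expect_identical(sum(encodingValues(bin) == 1), 3L)  # round(12 * 0.25)
  expect_true(all(encodingValues(bin) %in% c(0, 1)))
  expect_identical(encodingValues(bin),
                   encodingValues(exportFixedEncoding(
                     enc, mixed, binarize = TRUE, gamma = 0.25)))
  expect_error(exportFixedEncoding(enc, list()), "non-empty")
})
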