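test_that("radon is linear and matches the analytic oracle on a disk", {
  spec <- diskSpec(r = 0.5, mu = 0.3)
  img <- renderPhantom(spec, 256)
  g <- defaultGeometry(256, 180)
  v <- sinogramValues(radonTransform(img, g))
  # rotational symmetry of a centred disk: every column equal (to
  # discretisation accuracy)
  expect_lt(max(apply(v, 1, stats::sd)), 0.005)
  # analytic chord lengths on interior detectors, 2% relative
  sp <- detectorPositions(g)
  ana <- analyticProjection(spec, 0, sp)
  # interior detectors: away from the tangent band, where the chord
  # length has a square-root singularity
  interior <- ana > 0.1 * max(ana) &
    oracleInterior(spec, 0, sp, g@detectorSpacing)
  expect_lt(max(abs(v[interior, 1] - ana[interior]) / ana[interior]), 0.02)
  # linearity
  zero <- ctImage(matrix(0, 64, 64))
  g64 <- defaultGeometry(64, 20)
  expect_true(all(sinogramValues(radonTransform(zero, g64)) == 0))
  ph <- randomPhantom(64, 4, 2)$image
  s1 <- sinogramValues(radonTransform(ph, g64))
  s3 <- sinogramValues(radonTransform(ctImage(3 * imagePixels(ph)), g64))
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
})

test_that("degradation field implements the floored -log(beta) columns", {
  g <- ctGeometry(5, 4, 0.1)
  e <- projectionEncoding(c(1, exp(-2), 0, 0.5))
  fld <- degradationField(e, g, betaFloor = exp(-10))
  v <- fld@values
  expect_identical(dim(v), c(5L, 4L))
  expect_true(all(v[, 1] == 0))
  expect_equal(v[, 2], rep(2, 5), tolerance = 1e-12)
  expect_equal(v[, 3], rep(10, 5), tolerance = 1e-12)  # floor rule
  expect_equal(v[, 4], rep(-log(0.5), 5), tolerance = 1e-12)
  expect_error(degradationField(projectionEncoding(c(1, 1)), g), "length")
})

test_that("noise-free sparse measurement is exact superposition", {
  tc <- tinyCase()
  m2 <- nAngles(tc$geom)
  # identity at full dose
  ones <- projectionEncoding(rep(1, m2))
  out <- measureSparse(tc$sino, ones)
  expect_identical(sinogramValues(out), sinogramValues(tc$sino))
  # single-angle dose reduction shifts only that column, by exactly 1
  e <- rep(1, m2); e[5] <- exp(-1)
  out <- sinogramValues(measureSparse(tc$sino, projectionEncoding(e)))
  ref <- sinogramValues(tc$sino)
  expect_equal(out[, 5], ref[, 5] + 1, tolerance = 1e-15)
  expect_identical(out[, -5], ref[, -5])
  # superposition holds exactly for random encodings
  set.seed(4)
  for (i in 1:20) {
    e <- projectionEncoding(runif(m2))
    got <- sinogramValues(measureSparse(tc$sino, e)) -
      sinogramValues(tc$sino)
    expect_equal(got, degradationField(e, tc$geom)@values,
                 tolerance = 1e-15)
  }
})

test_that("measurement noise follows the photon-statistics scale", {
  # a constant sinogram gives i.i.d. entries: 10^4 draws of one
  # configuration, empirical sd within 5% of 1/sqrt(I0 beta exp(-M))
  g <- ctGeometry(100, 100, 0.1)
  M <- 1.2
  s <- sinogram(matrix(M, 100, 100), g)
  beta <- 0.3
  I0 <- 1e5
  out <- measureSparse(s, projectionEncoding(rep(beta, 100)),
                       photonModel(I0, TRUE), seed = 9)
  resid <- sinogramValues(out) - (M - log(beta))
  sigma <- 1 / sqrt(I0 * beta * exp(-M))
  expect_lt(abs(stats::sd(resid) - sigma) / sigma, 0.05)
  # seeded reproducibility
  out2 <- measureSparse(s, projectionEncoding(rep(beta, 100)),
                        photonModel(I0, TRUE), seed = 9)
  expect_identical(sinogramValues(out), sinogramValues(out2))
})

test_that("ramp filter has the |omega| frequency response", {
  r <- rampFilter(185)
  N <- length(r)
  expect_identical(N, 512L)              # next power of two above 2*m1
  expect_identical(r[1], 0)              # zero at DC
  expect_equal(r[2:N], rev(r[2:N]))      # symmetric
  expect_equal(which.max(r), N / 2 + 1)  # maximal at Nyquist
})

test_that("FBP round trip recovers the phantom and sharpens with angles", {
  ph <- sheppLoganPhantom(128)
  rec180 <- filteredBackprojection(
    radonTransform(ph, defaultGeometry(128, 180)))
  psnr180 <- imagePSNR(rec180, ph)
  expect_gte(psnr180, 25)
  rec30 <- filteredBackprojection(
    radonTransform(ph, defaultGeometry(128, 30)))
  expect_gt(psnr180, imagePSNR(rec30, ph))
})

test_that("FBP is linear and its adjoint matches (dot-product identity)", {
  g <- defaultGeometry(64, 60)
  set.seed(11)
  S <- matrix(runif(nDetectors(g) * nAngles(g)), nDetectors(g))
  f1 <- imagePixels(filteredBackprojection(sinogram(S, g), 64))
  f2 <- imagePixels(filteredBackprojection(sinogram(2.5 * S, g), 64))
  expect_equal(f2, 2.5 * f1, tolerance = 1e-12)
  expect_true(all(imagePixels(filteredBackprojection(
    sinogram(matrix(0, nDetectors(g), nAngles(g)), g), 64)) == 0))
  X <- matrix(rnorm(64 * 64), 64)
  lhs <- sum(f1 * X)
  rhs <- sum(sparseCT:::.fbpAdjoint(X, g, 64) * S)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})
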