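# Shared fixtures. Heavy training runs used by several acceptance checks
# are computed once on first use and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixtureOnce <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

tinyGeometry <- function(n = 16L, nAngles = 12L) defaultGeometry(n, nAngles)

diskSpec <- function(r = 0.5, mu = 0.3) {
  phantomSpec(data.frame(cx = 0, cy = 0, a = r, b = r, phi = 0, value = mu))
}

# small phantom + sinogram pair on a 16x16 grid (23 x 12 sinogram)
tinyCase <- function(seed = 3L) {
  fixtureOnce(paste0("tiny", seed), {
    g <- tinyGeometry()
    ph <- randomPhantom(16L, 4L, seed)
    list(geom = g, phantom = ph, sino = radonTransform(ph$image, g))
  })
}

# smoke-scale study configuration for the ablation / sampling comparison
# tier: 32x32 phantoms, 30 angles, 20% dose target, photon noise at
# I0 = 1e4 (see the methods vignette for the reasoning behind each value)
ablationConfig <- function() {
  trainingConfig(n = 32L, nAngles = 30L, gamma = 0.2, lr = 1e-3,
                 epochsStep2 = 12L, epochsStep3 = 20L, count = 30L,
                 batchSize = 4L, batchSizeStep3 = 2L, evalSubset = 6L,
                 kRange = c(3L, 7L), seed = 1L, noise = TRUE, I0 = 1e4)
}

# the dose-convergence configuration: 200 phantoms at 64x64, 60 angles
doseConvergenceConfig <- function() {
  trainingConfig(n = 64L, nAngles = 60L, gamma = 0.4, lr = 1e-3,
                 epochsStep2 = 2L, epochsStep3 = 1L, count = 200L,
                 batchSize = 4L, evalSubset = 4L, kRange = c(3L, 8L),
                 seed = 1L)
}

ablationRuns <- function() {
  fixtureOnce("ablationRuns", {
    cfg <- ablationConfig()
    s2 <- trainStep2(cfg)
    s3f <- trainStep3(cfg, s2, useProjNet = TRUE)
    s3i <- trainStep3(cfg, s2, useProjNet = FALSE)
    hold <- s2$prep$holdIdx
    ev2 <- sparseCT:::.evalStep2(s2$encoder, s2$projNet, s2$prep, hold)
    k <- max(1L, round(cfg$nAngles * ev2$dose))
    ei <- equalIntervalEncoding(cfg$nAngles, k / cfg$nAngles)
    s2e <- trainStep2(cfg, fixedEncoding = ei, prep = s2$prep)
    s3e <- trainStep3(cfg, s2e)
    list(cfg = cfg, s2 = s2, s3f = s3f, s3i = s3i, hold = hold,
         learnedDose = ev2$dose, ei = ei, s2e = s2e, s3e = s3e,
         full = sparseCT:::.evalImageArm(s3f$inputs, hold, s3f$imageNet),
         projOnly = sparseCT:::.evalImageArm(s3f$inputs, hold, NULL),
         imgOnly = sparseCT:::.evalImageArm(s3i$inputs, hold, s3i$imageNet),
         eiArm = sparseCT:::.evalImageArm(s3e$inputs, hold, s3e$imageNet))
  })
}

step2ConvergenceRun <- function() {
  fixtureOnce("step2Convergence", trainStep2(doseConvergenceConfig()))
}

# windowed reference computed per-pixel with explicit loops, kept fully
# independent of the separable-convolution implementation
.ssimBruteForce <- function(a, b, dataRange = 1) {
  g1 <- exp(-(-5:5)^2 / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  w <- outer(g1, g1)
  C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
  n1 <- nrow(a) - 10L; n2 <- ncol(a) - 10L
  acc <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    wa <- a[i:(i + 10), j:(j + 10)]
    wb <- b[i:(i + 10), j:(j + 10)]
    mx <- sum(w * wa); my <- sum(w * wb)
    vx <- sum(w * wa^2) - mx^2; vy <- sum(w * wb^2) - my^2
    cxy <- sum(w * wa * wb) - mx * my
    acc <- acc + ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  acc / (n1 * n2)
}


# random ellipse specification whose additive intensities can never exceed
# the [0,1] rendering clip (so the analytic chord-length oracle is exact)
randomOracleSpec <- function(k = 5L) {
  body <- data.frame(cx = runif(1, -0.05, 0.05), cy = runif(1, -0.05, 0.05),
                     a = runif(1, 0.7, 0.85), b = runif(1, 0.7, 0.85),
                     phi = runif(1, 0, pi), value = runif(1, 0.1, 0.15))
  inner <- data.frame(cx = runif(k, -0.4, 0.4), cy = runif(k, -0.4, 0.4),
                      a = runif(k, 0.05, 0.5), b = runif(k, 0.05, 0.5),
                      phi = runif(k, 0, pi), value = runif(k, 0.05, 0.15))
  phantomSpec(rbind(body, inner))
}

# detectors whose rays stay clear of every ellipse's tangent band: at a
# tangent ray the chord length has a square-root singularity that no
# finite-resolution rendering can match, so the oracle comparison is only
# meaningful away from them
oracleInterior <- function(spec, theta, sp, ds, pad = 2) {
  keep <- rep(TRUE, length(sp))
  e <- phantomEllipses(spec)
  for (k in seq_len(nrow(e))) {
    w <- sqrt((e$a[k] * cos(theta - e$phi[k]))^2 +
                (e$b[k] * sin(theta - e$phi[k]))^2)
    tc <- e$cx[k] * cos(theta) + e$cy[k] * sin(theta)
    keep <- keep & (abs(abs(sp - tc) - w) > pad * ds)
  }
  keep
}
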