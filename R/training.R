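# The three-step training procedure, its losses, the sparsity-bias
# calibration, and the ablation / sampling-scheme comparison drivers.

#' Training configuration
#'
#' Defaults follow the reference settings: base learning rate 1e-5, 3x3
#' kernels, batch size 4, dose penalty weight 1, epoch budgets 30/25. The
#' smoke-scale drivers in the tests and the acceptance script override the
#' sizes; see the methods vignette for the problem sizes used.
#'
#' @param n image side length (divisible by 16)
#' @param nAngles number of projection angles m2
#' @param gamma dose target in (0, 1]
#' @param lr Adam learning rate
#' @param epochsStep2,epochsStep3 epoch budgets for Steps 2 and 3
#' @param batchSize Step-2 minibatch size (>= 2; batch normalisation
#'   needs at least two samples, and small batches degrade its statistics)
#' @param batchSizeStep3 Step-3 minibatch size (>= 1); smaller batches
#'   give the image network more optimiser updates per epoch
#' @param doseWeight weight of the absolute dose-deviation penalty
#' @param seed master seed; all subsystem seeds derive from it
#' @param count number of phantoms in the generated dataset
#' @param kRange ellipse-count range for random phantoms
#' @param hidden hidden width of the encoder FCN
#' @param noise simulate photon noise in the measured sinograms?
#' @param I0 incident photons per ray at full dose
#' @param holdoutFraction held-out fraction (last part of the dataset)
#' @param evalSubset held-out samples used for the per-epoch metric curves
#' @return a validated named list
#' @export
trainingConfig <- function(n = 64L, nAngles = 60L, gamma = 0.4, lr = 1e-5,
                           epochsStep2 = 30L, epochsStep3 = 25L,
                           batchSize = 4L, batchSizeStep3 = 2L,
                           doseWeight = 1.0, seed = 0L,
                           count = 200L, kRange = c(3L, 8L), hidden = 256L,
                           noise = FALSE, I0 = 1e5,
                           holdoutFraction = 0.2, evalSubset = 8L) {
  if (n %% 16 != 0) stop("n must be divisible by 16")
  if (lr <= 0) stop("lr must be > 0")
  if (epochsStep2 < 1 || epochsStep3 < 1) stop("epochs must be >= 1")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (batchSize < 2) stop("batchSize must be >= 2")
  if (batchSizeStep3 < 1) stop("batchSizeStep3 must be >= 1")
  list(n = as.integer(n), nAngles = as.integer(nAngles), gamma = gamma,
       lr = lr, epochsStep2 = as.integer(epochsStep2),
       epochsStep3 = as.integer(epochsStep3),
       batchSize = as.integer(batchSize),
       batchSizeStep3 = as.integer(batchSizeStep3),
       doseWeight = doseWeight,
       seed = as.integer(seed), count = as.integer(count),
       kRange = as.integer(kRange), hidden = as.integer(hidden),
       noise = noise, I0 = I0, holdoutFraction = holdoutFraction,
       evalSubset = as.integer(evalSubset))
}

# Generate the dataset, project it, and fix the held-out split (the last
# holdoutFraction of the generated order, itself fixed by the seed).
# `sinos` are the clean line integrals (the supervision targets); `meas`
# are the measured full-dose sinograms the pipeline consumes — identical
# to `sinos` unless photon noise is enabled, in which case they carry the
# seeded Gaussian photon-statistics perturbation at full dose.
.prepareData <- function(config, dataset = NULL) {
  geom <- defaultGeometry(config$n, config$nAngles)
  if (is.null(dataset))
    dataset <- phantomDataset(config$count, config$n, config$kRange,
                              config$seed)
  sinos <- lapply(dataset, function(it) radonTransform(it$image, geom))
  meas <- if (isTRUE(config$noise)) {
    ones <- projectionEncoding(rep(1, config$nAngles))
    lapply(seq_along(sinos), function(i)
      measureSparse(sinos[[i]], ones, photonModel(config$I0, TRUE),
                    seed = .derivedSeed(config$seed, 555 + i)))
  } else sinos
  count <- length(dataset)
  nHold <- max(1L, floor(count * config$holdoutFraction))
  nHold <- min(nHold, count - 1L)
  holdIdx <- seq.int(count - nHold + 1L, count)
  trainIdx <- seq_len(count - nHold)
  list(dataset = dataset, sinos = sinos, meas = meas, geom = geom,
       trainIdx = trainIdx, holdIdx = holdIdx)
}

#' Step-2 loss: sinogram recovery error plus dose-deviation penalty
#'
#' Mean squared error between recovered and full-dose sinogram plus
#' \code{doseWeight * abs(doseFraction(e) - gamma)}.
#'
#' @param mRec,m recovered and reference sinograms (Sinogram or matrix)
#' @param encoding the sampling code (\linkS4class{ProjectionEncoding})
#' @param gamma dose target
#' @param doseWeight non-negative penalty weight
#' @return non-negative scalar
#' @export
lossProjection <- function(mRec, m, encoding, gamma, doseWeight = 1.0) {
  if (doseWeight < 0) stop("doseWeight must be >= 0")
  imageMSE(mRec, m) + doseWeight * doseDifference(encoding, gamma)
}

#' Step-3 loss: image reconstruction error
#'
#' Mean squared error between the restored and reference image; zero iff
#' identical.
#'
#' @param xRec,x restored and reference images (CTImage or matrix)
#' @return non-negative scalar
#' @export
lossImage <- function(xRec, x) imageMSE(xRec, x)

#' Step 1: calibrate the sparsity bias to a dose target
#'
#' The post-normalisation activations of the encoder do not depend on the
#' bias, so the batch-mean dose is a non-increasing, piecewise-linear
#' function of lambda'. Bisection on [0, max activation] finds the bias at
#' which the calibration batch's mean dose matches the target within
#' \code{tol} (or stops after \code{maxIter} iterations). Batch statistics
#' of the calibration batch are used (and returned, so they can seed the
#' running batch-normalisation state).
#'
#' @param params an \linkS4class{EncoderParams}
#' @param sinos non-empty list of \linkS4class{Sinogram}s (>= 2)
#' @param gamma dose target in (0, 1]
#' @param tol dose tolerance (default 0.01)
#' @param maxIter bisection iteration cap (default 60)
#' @return list with lambda, achievedDose, iterations and bnState
#' @export
calibrateLambda <- function(params, sinos, gamma, tol = 0.01,
                            maxIter = 60L) {
  if (length(sinos) == 0) stop("calibration batch must be non-empty")
  mats <- lapply(sinos, function(s) if (is(s, "Sinogram")) s@values else s)
  fw <- .encodeForward(params, mats, mode = "train")
  z <- fw$cache$Zn
  m2 <- params@dims$m2
  doseAt <- function(l) mean(colSums(pmin(pmax(z - l, 0), 1))) / m2
  d0 <- doseAt(0)
  bn <- list(mean = fw$cache$mu, var = fw$cache$va)
  if (d0 <= gamma) {
    if (gamma - d0 < tol)
      return(list(lambda = 0, achievedDose = d0, iterations = 0L,
                  bnState = bn))
    stop(sprintf(
      "dose target %.3f unreachable: achievable range at lambda >= 0 is [0, %.3f]",
      gamma, d0))
  }
  lo <- 0; hi <- max(z)
  lam <- hi; d <- doseAt(hi); it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    lam <- (lo + hi) / 2
    d <- doseAt(lam)
    if (abs(d - gamma) < tol) break
    if (d > gamma) lo <- lam else hi <- lam
  }
  list(lambda = lam, achievedDose = d, iterations = it, bnState = bn)
}

.chunks <- function(idx, size) {
  ch <- split(idx, ceiling(seq_along(idx) / size))
  n <- length(ch)
  if (n > 1L && length(ch[[n]]) == 1L) {   # BN needs batches of >= 2
    ch[[n - 1L]] <- c(ch[[n - 1L]], ch[[n]])
    ch[[n]] <- NULL
  }
  ch
}

# sinogram-domain metrics of the (frozen-mode) G1 o G2' pipeline
.evalStep2 <- function(enc, pr, prep, idx, fixedEncoding = NULL) {
  res <- vapply(idx, function(i) {
    M <- prep$sinos[[i]]@values
    Mm <- prep$meas[[i]]@values
    e <- if (is.null(fixedEncoding))
      encodeProjections(enc, prep$meas[[i]], "eval")@e else fixedEncoding@e
    mhat <- sweep(Mm, 2, e, "*")
    mrec <- .projFwd(pr, mhat, wantCache = FALSE)$out
    dr <- max(abs(M), 1e-8)
    c(imageSSIM(mrec, M, dr), imagePSNR(mrec, M, dr), imageMSE(mrec, M),
      sum(e) / length(e))
  }, numeric(4))
  list(ssim = mean(res[1, ]), psnr = mean(res[2, ]), mse = mean(res[3, ]),
       dose = mean(res[4, ]))
}

#' Step 2: train the encoder and the sinogram-recovery network
#'
#' Calibrates the sparsity bias (Step 1), then minimises the Step-2 loss
#' with Adam over seeded, shuffled minibatches. The bias is held fixed;
#' the dose penalty performs the fine adjustment. Running BN statistics
#' update with momentum 0.1 throughout and freeze afterwards. The history
#' records per-epoch mean loss, the dose difference, and sinogram-domain
#' quality metrics on a held-out subset.
#'
#' @param config a \code{\link{trainingConfig}}
#' @param dataset optional pre-generated phantom dataset (list of
#'   \code{list(image, spec)}); generated from the config when NULL
#' @param fixedEncoding optional \linkS4class{ProjectionEncoding}; when
#'   given the encoder is bypassed (fixed sampling scheme) and only G2' is
#'   trained, with no dose penalty
#' @param prep internal: reuse a prepared dataset
#' @return list with encoder, projNet, history (data.frame), lambda,
#'   and the prepared data (prep)
#' @export
trainStep2 <- function(config, dataset = NULL, fixedEncoding = NULL,
                       prep = NULL) {
  if (is.null(prep)) prep <- .prepareData(config, dataset)
  geom <- prep$geom
  m2 <- geom@nAngles
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  enc <- newEncoderParams(geom, config$hidden,
                          seed = .derivedSeed(config$seed, 11))
  pr <- newProjReconParams(seed = .derivedSeed(config$seed, 12))
  lam <- 0
  if (is.null(fixedEncoding)) {
    calIdx <- utils::head(prep$trainIdx, 16L)
    cal <- calibrateLambda(enc, prep$meas[calIdx], config$gamma)
    enc@lambdaBias <- cal$lambda
    enc@bnState <- cal$bnState
    lam <- cal$lambda
  }
  adE <- .adamInit(enc@weights)
  adP <- .adamInit(pr@layers)
  set.seed(.derivedSeed(config$seed, 21))
  evalIdx <- utils::head(prep$holdIdx, config$evalSubset)
  hist <- vector("list", config$epochsStep2)
  for (ep in seq_len(config$epochsStep2)) {
    perm <- sample(prep$trainIdx)
    epLoss <- 0; epDose <- 0; nb <- 0L; ns <- 0L
    for (batch in .chunks(perm, config$batchSize)) {
      Min <- lapply(batch, function(i) prep$meas[[i]]@values)
      Mt <- lapply(batch, function(i) prep$sinos[[i]]@values)
      B <- length(Min)
      if (is.null(fixedEncoding)) {
        fw <- .encodeForward(enc, Min, mode = "train")
        enc@bnState <- list(mean = fw$runMean, var = fw$runVar)
        E <- fw$E
      } else {
        E <- matrix(fixedEncoding@e, m2, B)
      }
      gP <- NULL
      dE <- matrix(0, m2, B)
      bLoss <- 0
      for (b in seq_len(B)) {
        mhat <- sweep(Min[[b]], 2, E[, b], "*")
        pf <- .projFwd(pr, mhat)
        diffb <- pf$out - Mt[[b]]
        ds <- sum(E[, b]) / m2
        bLoss <- bLoss + mean(diffb^2) / B
        if (is.null(fixedEncoding))
          bLoss <- bLoss + config$doseWeight * abs(ds - config$gamma) / B
        dM <- 2 * diffb / length(diffb) / B
        pb <- .projBwd(pr, pf$cache, dM)
        gP <- if (is.null(gP)) pb$grads else .tadd(gP, pb$grads)
        dE[, b] <- colSums(pb$dx * Min[[b]]) +
          config$doseWeight * sign(ds - config$gamma) / m2 / B
        epDose <- epDose + ds; ns <- ns + 1L
      }
      if (!is.finite(bLoss))
        stop("training diverged: non-finite Step-2 loss at epoch ", ep)
      if (is.null(fixedEncoding)) {
        gE <- .encodeBackward(enc, fw$cache, dE)
        upd <- .adamStep(enc@weights, gE, adE, config$lr)
        enc@weights <- upd$w; adE <- upd$state
      }
      upd <- .adamStep(pr@layers, gP, adP, config$lr)
      pr@layers <- upd$w; adP <- upd$state
      epLoss <- epLoss + bLoss; nb <- nb + 1L
    }
    ev <- .evalStep2(enc, pr, prep, evalIdx, fixedEncoding)
    hist[[ep]] <- data.frame(
      epoch = ep, loss = epLoss / nb,
      doseDiff = abs(epDose / ns - config$gamma),
      ssim = ev$ssim, psnr = ev$psnr, mse = ev$mse)
  }
  list(encoder = enc, projNet = pr, history = do.call(rbind, hist),
       lambda = lam, fixedEncoding = fixedEncoding, prep = prep)
}

# precompute the Step-3 input images (frozen G1 o G2' in eval mode)
.step3Inputs <- function(config, prep, enc, pr, fixedEncoding = NULL,
                         useProjNet = TRUE) {
  n <- config$n
  g <- prep$geom
  lapply(seq_along(prep$meas), function(i) {
    Mm <- prep$meas[[i]]@values
    e <- if (is.null(fixedEncoding))
      encodeProjections(enc, prep$meas[[i]], "eval")@e else fixedEncoding@e
    mhat <- sweep(Mm, 2, e, "*")
    mrec <- if (useProjNet) .projFwd(pr, mhat, wantCache = FALSE)$out else mhat
    xdeg <- filteredBackprojection(sinogram(mrec, g), n)@pixels
    list(x = xdeg, target = prep$dataset[[i]]$image@pixels, dose = mean(e))
  })
}

.evalStep3 <- function(ir, inputs, idx) {
  res <- vapply(idx, function(i) {
    y <- .imgFwd(ir, inputs[[i]]$x)$out
    t <- inputs[[i]]$target
    c(imageSSIM(y, t), imagePSNR(y, t), imageMSE(y, t))
  }, numeric(3))
  list(ssim = mean(res[1, ]), psnr = mean(res[2, ]), mse = mean(res[3, ]))
}

#' Step 3: train the image detail-restoration network
#'
#' Takes the output of the frozen sub-network G1 o G2' (through FBP) as
#' input and minimises the image MSE with Adam. Step-2 parameters are not
#' updated. The history records per-epoch loss and held-out image metrics.
#'
#' @param config a \code{\link{trainingConfig}}
#' @param frozen result of \code{\link{trainStep2}} (encoder + projNet +
#'   prep), left untouched
#' @param useProjNet when FALSE the recovery network is bypassed and G2''
#'   is trained directly on the FBP of the encoded sparse sinogram (the
#'   image-domain-only ablation arm)
#' @return list with imageNet, history, and the precomputed inputs
#' @export
trainStep3 <- function(config, frozen, useProjNet = TRUE) {
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  prep <- frozen$prep
  inputs <- .step3Inputs(config, prep, frozen$encoder, frozen$projNet,
                         frozen$fixedEncoding, useProjNet)
  ir <- newImageReconParams(seed = .derivedSeed(config$seed, 13))
  adI <- .adamInit(ir@layers)
  set.seed(.derivedSeed(config$seed, 31))
  evalIdx <- utils::head(prep$holdIdx, config$evalSubset)
  hist <- vector("list", config$epochsStep3)
  for (ep in seq_len(config$epochsStep3)) {
    perm <- sample(prep$trainIdx)
    epLoss <- 0; nb <- 0L
    for (batch in .chunks(perm, config$batchSizeStep3)) {
      B <- length(batch)
      gI <- NULL
      bLoss <- 0
      for (b in batch) {
        fwd <- .imgFwd(ir, inputs[[b]]$x)
        diffb <- fwd$out - inputs[[b]]$target
        bLoss <- bLoss + mean(diffb^2) / B
        ib <- .imgBwd(ir, fwd$cache, 2 * diffb / length(diffb) / B)
        gI <- if (is.null(gI)) ib$grads else .tadd(gI, ib$grads)
      }
      if (!is.finite(bLoss))
        stop("training diverged: non-finite Step-3 loss at epoch ", ep)
      upd <- .adamStep(ir@layers, gI, adI, config$lr)
      ir@layers <- upd$w; adI <- upd$state
      epLoss <- epLoss + bLoss; nb <- nb + 1L
    }
    ev <- .evalStep3(ir, inputs, evalIdx)
    hist[[ep]] <- data.frame(epoch = ep, loss = epLoss / nb,
                             ssim = ev$ssim, psnr = ev$psnr, mse = ev$mse)
  }
  list(imageNet = ir, history = do.call(rbind, hist), inputs = inputs)
}

#' Run the full three-step training procedure
#'
#' Step 1 calibrates the sparsity bias, Step 2 trains G1 and G2', Step 3
#' trains G2'' on the frozen Step-2 output. Returns the joint model, both
#' histories, and an evaluation report on the held-out split.
#'
#' @param config a \code{\link{trainingConfig}}
#' @param dataset optional pre-generated phantom dataset
#' @return list with model (\linkS4class{JointModel}), historyStep2,
#'   historyStep3 and report
#' @export
runJointTraining <- function(config, dataset = NULL) {
  s2 <- trainStep2(config, dataset)
  s3 <- trainStep3(config, s2)
  model <- new("JointModel", encoder = s2$encoder, projNet = s2$projNet,
               imageNet = s3$imageNet, geometry = s2$prep$geom,
               config = config)
  report <- .evaluateHoldout(model, s2$prep, config)
  list(model = model, historyStep2 = s2$history, historyStep3 = s3$history,
       report = report, prep = s2$prep)
}

.evaluateHoldout <- function(model, prep, config) {
  res <- lapply(prep$holdIdx, function(i) {
    jf <- jointReconstruct(model, prep$meas[[i]])
    t <- prep$dataset[[i]]$image@pixels
    y <- jf$image@pixels
    c(ssim = imageSSIM(y, t), psnr = imagePSNR(y, t), mse = imageMSE(y, t),
      dose = doseFraction(jf$encoding))
  })
  m <- do.call(rbind, res)
  list(ssim = mean(m[, "ssim"]), psnr = mean(m[, "psnr"]),
       mse = mean(m[, "mse"]), doseFraction = mean(m[, "dose"]),
       doseDifference = abs(mean(m[, "dose"]) - config$gamma),
       nHoldout = length(prep$holdIdx))
}

.evalImageArm <- function(inputs, idx, ir = NULL) {
  res <- vapply(idx, function(i) {
    y <- if (is.null(ir)) inputs[[i]]$x else .imgFwd(ir, inputs[[i]]$x)$out
    t <- inputs[[i]]$target
    c(imageSSIM(y, t), imagePSNR(y, t), imageMSE(y, t))
  }, numeric(3))
  c(ssim = mean(res[1, ]), psnr = mean(res[2, ]), mse = mean(res[3, ]))
}

#' Ablation experiment: both reconstruction domains are necessary
#'
#' Trains and evaluates, under identical budgets on the same split, the
#' full pipeline G1 o G2' o G2'', the projection-domain-only arm G1 o G2'
#' (FBP of the recovered sinogram), and the image-domain-only arm
#' G1 o G2'' (FBP of the encoded sparse sinogram fed to G2'').
#'
#' @param config a \code{\link{trainingConfig}}
#' @param dataset optional pre-generated phantom dataset
#' @return list with table (data.frame of three arms x three metrics) and
#'   the underlying runs
#' @export
runAblation <- function(config, dataset = NULL) {
  s2 <- trainStep2(config, dataset)
  s3full <- trainStep3(config, s2, useProjNet = TRUE)
  s3img <- trainStep3(config, s2, useProjNet = FALSE)
  hold <- s2$prep$holdIdx
  full <- .evalImageArm(s3full$inputs, hold, s3full$imageNet)
  projOnly <- .evalImageArm(s3full$inputs, hold, NULL)
  imgOnly <- .evalImageArm(s3img$inputs, hold, s3img$imageNet)
  tab <- data.frame(
    arm = c("G1.G2p.G2pp", "G1.G2p", "G1.G2pp"),
    ssim = c(full["ssim"], projOnly["ssim"], imgOnly["ssim"]),
    psnr = c(full["psnr"], projOnly["psnr"], imgOnly["psnr"]),
    mse = c(full["mse"], projOnly["mse"], imgOnly["mse"]),
    row.names = NULL)
  list(table = tab, step2 = s2, step3Full = s3full, step3Image = s3img)
}

#' Learned versus equal-interval sampling at matched dose
#'
#' Runs the full learned-encoding pipeline, then an equal-interval
#' baseline whose kept-angle count is matched to the learned pipeline's
#' achieved dose (within half an angle, i.e. < 0.01 for the geometries
#' used), trained under identical budgets, and compares held-out image
#' quality.
#'
#' @param config a \code{\link{trainingConfig}}
#' @param dataset optional pre-generated phantom dataset
#' @return list with table (two schemes x dose + three metrics) and runs
#' @export
compareSampling <- function(config, dataset = NULL) {
  learned <- runJointTraining(config, dataset)
  m2 <- config$nAngles
  k <- max(1L, round(m2 * learned$report$doseFraction))
  ei <- equalIntervalEncoding(m2, k / m2)
  s2e <- trainStep2(config, fixedEncoding = ei, prep = learned$prep)
  s3e <- trainStep3(config, s2e)
  hold <- learned$prep$holdIdx
  eiEval <- .evalImageArm(s3e$inputs, hold, s3e$imageNet)
  tab <- data.frame(
    scheme = c("learned", "equal-interval"),
    doseFraction = c(learned$report$doseFraction, doseFraction(ei)),
    ssim = c(learned$report$ssim, eiEval["ssim"]),
    psnr = c(learned$report$psnr, eiEval["psnr"]),
    mse = c(learned$report$mse, eiEval["mse"]),
    row.names = NULL)
  list(table = tab, learned = learned, equalInterval = list(
    step2 = s2e, step3 = s3e, encoding = ei))
}
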