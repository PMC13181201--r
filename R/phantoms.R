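# Synthetic ellipse phantoms with analytically known projections.

# Standard head phantom ellipse table (contrast-enhanced variant):
# value, a, b, cx, cy, phi (degrees)
.sheppLoganTable <- function() {
  m <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)
  data.frame(cx = m[, 4], cy = m[, 5], a = m[, 2], b = m[, 3],
             phi = m[, 6] * pi / 180, value = m[, 1])
}

#' Render a phantom specification to an image
#'
#' Ellipse intensities are additive; the summed image is clipped to [0,1].
#' Pixel centres lie on a uniform grid over \eqn{[-1,1]^2}, row index
#' increasing downward. Each pixel is the mean of an
#' \code{oversample x oversample} subpixel grid, so ellipse boundaries are
#' anti-aliased and the rendered image tracks the analytic line-integral
#' model to sub-pixel accuracy. Rendering is deterministic.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param n image side length (n >= 16)
#' @param oversample subpixel factor per axis (>= 1, default 4)
#' @return a \linkS4class{CTImage}
#' @export
renderPhantom <- function(spec, n, oversample = 4L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 16L)
    stop("n must be a single integer >= 16")
  os <- as.integer(oversample)
  if (os < 1L) stop("oversample must be >= 1")
  stopifnot(is(spec, "PhantomSpec"))
  N <- n * os
  pxf <- 2 / N
  c0 <- (N + 1) / 2
  xs <- (seq_len(N) - c0) * pxf         # column coordinate
  ys <- -(seq_len(N) - c0) * pxf        # row coordinate (downward)
  img <- matrix(0, N, N)
  X <- matrix(xs, N, N, byrow = TRUE)
  Y <- matrix(ys, N, N)
  e <- spec@ellipses
  for (k in seq_len(nrow(e))) {
    ct <- cos(e$phi[k]); st <- sin(e$phi[k])
    dx <- X - e$cx[k]; dy <- Y - e$cy[k]
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    inside <- (u / e$a[k])^2 + (v / e$b[k])^2 <= 1
    img <- img + e$value[k] * inside
  }
  img <- pmin(pmax(img, 0), 1)
  if (os > 1L) {
    m1 <- matrix(colMeans(matrix(img, nrow = os)), nrow = n)    # n x N
    img <- t(matrix(colMeans(matrix(t(m1), nrow = os)), nrow = n))
  }
  ctImage(img, 2 / n)
}

#' Standard head phantom
#'
#' The classic 10-ellipse head phantom rendered at n x n with additive
#' intensities clipped to [0,1].
#'
#' @param n image side length (n >= 16)
#' @return a \linkS4class{CTImage}
#' @examples
#' img <- sheppLoganPhantom(64)
#' range(imagePixels(img))
#' @export
sheppLoganPhantom <- function(n) {
  renderPhantom(sheppLoganSpec(), n)
}

#' Specification of the standard head phantom
#' @return a \linkS4class{PhantomSpec} with 10 ellipses
#' @export
sheppLoganSpec <- function() phantomSpec(.sheppLoganTable())

#' Random piecewise-constant ellipse phantom
#'
#' Draws \code{k} ellipses with parameters from fixed documented ranges.
#' When \code{k >= 1} the first ellipse is an enclosing "body" (semi-axes in
#' [0.7, 0.85], centred); the rest are interior structures with semi-axes in
#' [0.05, 0.5] and centres in [-0.4, 0.4]. All intensities are drawn from
#' [0.1, 0.5]. Output is deterministic given \code{(n, k, seed)}.
#'
#' @param n image side length (n >= 16)
#' @param k number of ellipses (k >= 0)
#' @param seed integer RNG seed
#' @return list with elements \code{image} (\linkS4class{CTImage}) and
#'   \code{spec} (\linkS4class{PhantomSpec})
#' @export
randomPhantom <- function(n, k, seed) {
  if (length(k) != 1L || is.na(k) || k < 0) stop("k must be >= 0")
  k <- as.integer(k)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  if (k == 0L) {
    spec <- phantomSpec()
  } else {
    cx <- c(runif(1, -0.05, 0.05), runif(k - 1L, -0.4, 0.4))
    cy <- c(runif(1, -0.05, 0.05), runif(k - 1L, -0.4, 0.4))
    a <- c(runif(1, 0.7, 0.85), runif(k - 1L, 0.05, 0.5))
    b <- c(runif(1, 0.7, 0.85), runif(k - 1L, 0.05, 0.5))
    phi <- runif(k, 0, pi)
    value <- runif(k, 0.1, 0.5)
    spec <- phantomSpec(data.frame(cx = cx, cy = cy, a = a, b = b,
                                   phi = phi, value = value))
  }
  list(image = renderPhantom(spec, n), spec = spec)
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.derivedSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Generate a reproducible phantom dataset
#'
#' Per-item seeds are derived deterministically from the master seed
#' (\code{(seed + 7919 * i) mod 2^31-1}); item i equals
#' \code{randomPhantom(n, k_i, derivedSeed_i)}, with the ellipse counts
#' \code{k_i} drawn upfront under the master seed.
#'
#' @param count number of phantoms (>= 1)
#' @param n image side length
#' @param kRange length-2 integer range of ellipse counts (inclusive)
#' @param seed master seed
#' @return list of \code{count} items, each a list(image, spec)
#' @export
phantomDataset <- function(count, n, kRange = c(3L, 8L), seed = 0L) {
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("count must be >= 1")
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  ks <- sample(seq.int(kRange[1], kRange[2]), count, replace = TRUE)
  lapply(seq_len(count), function(i)
    randomPhantom(n, ks[i], .derivedSeed(seed, i)))
}

#' Analytic line integral through an ellipse phantom
#'
#' Closed-form chord-length evaluation of the line integral along the ray
#' with angle \code{theta} and signed detector offset \code{s}: the sum over
#' ellipses of intensity times chord length. Serves as the independent
#' oracle for the discrete radon operator. Note this evaluates the additive
#' ellipse model without the [0,1] rendering clip.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param theta projection angle in radians
#' @param s detector coordinate(s), vectorised
#' @return numeric vector of line-integral values, same length as \code{s}
#' @export
analyticProjection <- function(spec, theta, s) {
  stopifnot(is(spec, "PhantomSpec"))
  e <- spec@ellipses
  out <- numeric(length(s))
  for (k in seq_len(nrow(e))) {
    tk <- theta - e$phi[k]
    w2 <- (e$a[k] * cos(tk))^2 + (e$b[k] * sin(tk))^2
    sk <- s - (e$cx[k] * cos(theta) + e$cy[k] * sin(theta))
    d2 <- w2 - sk^2
    hit <- d2 > 0
    out[hit] <- out[hit] +
      e$value[k] * 2 * e$a[k] * e$b[k] * sqrt(d2[hit]) / w2
  }
  out
}
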