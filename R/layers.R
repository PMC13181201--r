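# Layer metadata, weight initialisation, parameter-tree utilities and the
# Adam optimiser. Tensors are (H, W, C) arrays; the heavy lifting lives in
# the compiled primitives.

.meta <- function(type, Cin, Cout, k, stride = 1L, pad = 0L,
                  act = "relu", init = "he") {
  list(type = type, Cin = Cin, Cout = Cout, k = k,
       stride = as.integer(stride), pad = as.integer(pad), act = act,
       init = init)
}

# He-uniform initialisation; fan-in = Cin * k^2 for both layer kinds.
# Parametric-ReLU layers carry one shared negative slope (initial 0.25,
# the back-projection-network convention) that trains with the weights.
.initLayer <- function(m) {
  fan <- m$Cin * m$k * m$k
  lim <- sqrt(6 / fan)
  W <- if (m$type == "conv")
    matrix(runif(m$Cout * fan, -lim, lim), m$Cout, fan)
  else
    matrix(runif(m$Cin * m$Cout * m$k * m$k, -lim, lim),
           m$Cin, m$Cout * m$k * m$k)
  if (identical(m$init, "zero")) W[] <- 0
  out <- list(W = W, b = numeric(m$Cout))
  if (identical(m$act, "prelu")) out$a <- 0.25
  out
}

.layF <- function(m, w, x) {
  if (m$type == "conv")
    cpp_conv2d(x, w$W, w$b, m$k, m$k, m$stride, m$pad)
  else
    cpp_convT2d(x, w$W, w$b, m$k, m$k, m$stride, m$pad, m$Cout)
}

.layB <- function(m, w, x, dy) {
  if (m$type == "conv")
    cpp_conv2d_bwd(x, w$W, dy, m$k, m$k, m$stride, m$pad)
  else
    cpp_convT2d_bwd(x, w$W, dy, m$k, m$k, m$stride, m$pad)
}

.cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

.slice3 <- function(x, from, to) {
  x[, , from:to, drop = FALSE]
}

# ---- parameter trees -----------------------------------------------------

# map f over 1-3 parallel trees of numeric leaves
.tmap <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a))
      out[[i]] <- .tmap(f, a[[i]],
                        if (!is.null(b)) b[[i]],
                        if (!is.null(c)) c[[i]])
    out
  } else f(a, b, c)
}

.tzero <- function(a) .tmap(function(x, ...) x * 0, a)
.tadd <- function(a, b) .tmap(function(x, y, ...) x + y, a, b)
.tscale <- function(a, s) .tmap(function(x, ...) x * s, a)

.adamInit <- function(w) list(m = .tzero(w), v = .tzero(w), t = 0L)

.adamStep <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- .tmap(function(m, gg, ...) beta1 * m + (1 - beta1) * gg, st$m, g)
  st$v <- .tmap(function(v, gg, ...) beta2 * v + (1 - beta2) * gg^2, st$v, g)
  c1 <- 1 / (1 - beta1^st$t)
  c2 <- 1 / (1 - beta2^st$t)
  w <- .tmap(function(wv, m, v) wv - lr * (m * c1) / (sqrt(v * c2) + eps),
             w, st$m, st$v)
  list(w = w, state = st)
}

#' Zero all weights of a network parameter object
#'
#' Utility mainly useful for verifying the residual-identity property of
#' the sinogram-recovery network.
#'
#' @param params a \linkS4class{ProjReconParams} or
#'   \linkS4class{ImageReconParams}
#' @return the same object with every weight and bias set to zero
#' @export
zeroedParams <- function(params) {
  params@layers <- .tzero(params@layers)
  params
}
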