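# Minimal dense/convolutional network core.
#
# No automatic differentiation library is assumed: layers are implemented as
# matrix operations (convolution by im2col + GEMM) with hand-derived
# backward passes, and parameters are updated with Adam. Batches are stored
# as [n x d] matrices; multi-channel images are flattened channel-fastest,
# i.e. element (c, h, w) of a C x H x W array sits at ((h-1)*W + w-1)*C + c.

flatten_chw <- function(a) {
  # a: array [C x H x W] -> flat vector in the layout above
  as.vector(aperm(a, c(1L, 3L, 2L)))
}

# Precomputed gather/scatter maps for one convolution shape.
conv_map <- function(C, H, W, kh, kw, sh, sw, ph, pw) {
  OH <- (H + 2L * ph - kh) %/% sh + 1L
  OW <- (W + 2L * pw - kw) %/% sw + 1L
  if (OH < 1L || OW < 1L)
    abort_input(sprintf("convolution output collapses: input %dx%d, kernel %dx%d", H, W, kh, kw))
  op <- OH * OW
  K <- C * kh * kw
  idx <- matrix(NA_integer_, op, K)
  for (oh in seq_len(OH)) for (ow in seq_len(OW)) {
    o <- (oh - 1L) * OW + ow
    k <- 0L
    for (ki in seq_len(kh)) for (kj in seq_len(kw)) for (cc in seq_len(C)) {
      k <- k + 1L
      h <- (oh - 1L) * sh + ki - ph
      w <- (ow - 1L) * sw + kj - pw
      if (h >= 1L && h <= H && w >= 1L && w <= W)
        idx[o, k] <- ((h - 1L) * W + (w - 1L)) * C + cc
    }
  }
  D <- C * H * W
  idxv <- as.vector(idx)
  pad <- is.na(idxv)
  idxv[pad] <- D + 1L
  nz <- which(!pad)
  scatter <- Matrix::sparseMatrix(i = nz, j = idxv[nz], x = 1, dims = c(op * K, D))
  list(C = C, H = H, W = W, OH = OH, OW = OW, op = op, K = K, D = D,
       idxv = idxv, scatter = scatter)
}

# X: [n x D]; Wm: [OC x K]; returns output [n x OC*op] plus im2col cache.
conv_forward <- function(X, Wm, b, map) {
  n <- nrow(X)
  OC <- nrow(Wm)
  cols <- cbind(X, 0)[, map$idxv, drop = FALSE]
  dim(cols) <- c(n * map$op, map$K)
  Z <- cols %*% t(Wm)
  Z <- Z + rep(b, each = n * map$op)
  Y <- aperm(array(Z, c(n, map$op, OC)), c(1L, 3L, 2L))
  dim(Y) <- c(n, OC * map$op)
  list(out = Y, cols = cols)
}

conv_backward <- function(dY, cols, Wm, map, n) {
  OC <- nrow(Wm)
  dZ <- aperm(array(dY, c(n, OC, map$op)), c(1L, 3L, 2L))
  dim(dZ) <- c(n * map$op, OC)
  dW <- t(dZ) %*% cols
  db <- colSums(dZ)
  dcols <- dZ %*% Wm
  dim(dcols) <- c(n, map$op * map$K)
  dX <- as.matrix(dcols %*% map$scatter)
  list(dX = dX, dW = dW, db = db)
}

dense_forward <- function(X, W, b) X %*% W + rep(b, each = nrow(X))

dense_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = t(X) %*% dY, db = colSums(dY))
}

leaky_relu <- function(x, slope) {
  p <- x > 0
  x * p + slope * x * (1 - p)
}

leaky_relu_grad <- function(x, slope) {
  p <- x > 0
  p + slope * (1 - p)
}

# Inverted dropout; returns scaled activations and the mask used.
dropout_forward <- function(x, rate) {
  if (rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim = dim(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
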