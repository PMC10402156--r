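# Minimal neural-network primitives with explicit backward passes.
#
# Everything operates on matrices "positions x channels" (1D) or arrays
# "H x W x channels" (2D). Convolutions use same-padding im2col so the heavy
# lifting is BLAS matrix multiplication; each forward returns the cache its
# backward needs. No framework is available in this environment, so the
# layer set is deliberately small: conv1d, conv2d, per-example normalization,
# ReLU, average pooling, linear, outer-concatenation. Hot paths avoid
# sweep()/aperm() in favor of rep()-based recycling and row-index im2col.

he_init <- function(n_in, n_out, fan) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan)), n_in, n_out)
}

# add a per-channel bias to a positions x channels matrix
add_bias <- function(y, b) {
  if (all(b == 0)) return(y)
  y + rep(b, each = nrow(y))
}

# Convolutions are computed as a sum of k shifted GEMMs against the padded
# input; only the padded input is cached, not an im2col expansion, which
# keeps the training-time cache small.

pad1d <- function(x, p) {
  Cin <- ncol(x)
  rbind(matrix(0, p, Cin), x, matrix(0, p, Cin))
}

conv1d_fwd <- function(x, W, b, k) {
  L <- nrow(x); Cin <- ncol(x); p <- (k - 1L) %/% 2L
  xp <- pad1d(x, p)
  y <- NULL
  for (o in 0:(k - 1L)) {
    rows <- (o * Cin + 1L):((o + 1L) * Cin)
    term <- xp[(1L + o):(L + o), , drop = FALSE] %*% W[rows, , drop = FALSE]
    y <- if (is.null(y)) term else y + term
  }
  list(y = add_bias(y, b),
       cache = list(xp = xp, L = L, Cin = Cin, k = k))
}

conv1d_bwd <- function(dy, W, cache) {
  L <- cache$L; Cin <- cache$Cin; k <- cache$k
  p <- (k - 1L) %/% 2L
  xp <- cache$xp
  dW <- matrix(0, k * Cin, ncol(W))
  dxp <- matrix(0, L + 2L * p, Cin)
  for (o in 0:(k - 1L)) {
    rows <- (o * Cin + 1L):((o + 1L) * Cin)
    sl <- (1L + o):(L + o)
    dW[rows, ] <- crossprod(xp[sl, , drop = FALSE], dy)
    dxp[sl, ] <- dxp[sl, ] + dy %*% t(W[rows, , drop = FALSE])
  }
  list(dx = dxp[(p + 1L):(p + L), , drop = FALSE], dW = dW,
       db = colSums(dy))
}

# per-example normalization over positions (batch statistics at batch size 1)
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  L <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = L)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = L)
  y <- xhat * rep(gamma, each = L) + rep(beta, each = L)
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma, N = L))
}

inorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$gamma; N <- cache$N
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(g, each = N)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(m1, each = N) - xhat * rep(m2, each = N)) *
    rep(inv, each = N)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bwd <- function(dy, cache) dy * cache

avgpool1d_fwd <- function(x, f) {
  L <- nrow(x)
  if (L %% f != 0) stop("pool factor must divide the length")
  grp <- rep(seq_len(L %/% f), each = f)
  y <- rowsum(x, grp, reorder = FALSE) / f
  list(y = y, cache = list(L = L, f = f))
}

avgpool1d_bwd <- function(dy, cache) {
  dy[rep(seq_len(nrow(dy)), each = cache$f), , drop = FALSE] / cache$f
}

conv2d_offsets <- function(k) {
  g <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L))
  g[order(g$dj, g$di), ]
}

# row indices of every output pixel in the (H+2p) x (W+2p) padded plane,
# flattened column-major; offset (di, dj) adds dj*Hp + di
conv2d_base_idx <- function(H, W, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  as.vector(outer(seq_len(H), (0:(W - 1L)) * Hp, "+"))
}

pad2d <- function(x, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  xp <- matrix(0, Hp * Wp, Cin)
  inner <- as.vector(outer(p + seq_len(H), (p + seq_len(W) - 1L) * Hp, "+"))
  dim(x) <- c(H * W, Cin)
  xp[inner, ] <- x
  xp
}

conv2d_fwd <- function(x, W, b, k) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  Hp <- H + k - 1L
  xp <- pad2d(x, k)
  base <- conv2d_base_idx(H, Wd, k)
  offs <- conv2d_offsets(k)
  y <- NULL
  for (o in seq_len(nrow(offs))) {
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    idx <- base + offs$dj[o] * Hp + offs$di[o]
    term <- xp[idx, , drop = FALSE] %*% W[rows, , drop = FALSE]
    y <- if (is.null(y)) term else y + term
  }
  y <- add_bias(y, b)
  dim(y) <- c(H, Wd, ncol(W))
  list(y = y, cache = list(xp = xp, H = H, W = Wd, Cin = Cin, k = k))
}

conv2d_bwd <- function(dy, W, cache) {
  H <- cache$H; Wd <- cache$W; Cin <- cache$Cin; k <- cache$k
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- Wd + 2L * p
  dim(dy) <- c(H * Wd, ncol(W))
  base <- conv2d_base_idx(H, Wd, k)
  offs <- conv2d_offsets(k)
  dW <- matrix(0, k^2 * Cin, ncol(W))
  dxp <- matrix(0, Hp * Wp, Cin)
  for (o in seq_len(nrow(offs))) {
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    idx <- base + offs$dj[o] * Hp + offs$di[o]
    dW[rows, ] <- crossprod(cache$xp[idx, , drop = FALSE], dy)
    dxp[idx, ] <- dxp[idx, ] + dy %*% t(W[rows, , drop = FALSE])
  }
  inner <- as.vector(outer(p + seq_len(H), (p + seq_len(Wd) - 1L) * Hp, "+"))
  dx <- dxp[inner, , drop = FALSE]
  dim(dx) <- c(H, Wd, Cin)
  list(dx = dx, dW = dW, db = colSums(dy))
}

linear_fwd <- function(x, W, b) {
  list(y = add_bias(x %*% W, b), cache = x)
}

linear_bwd <- function(dy, W, cache) {
  list(dx = dy %*% t(W), dW = crossprod(cache, dy), db = colSums(dy))
}

#' Outer-concatenation of per-position features
#'
#' Lifts an `L x C` feature matrix to an `L x L x 2C` pairwise array with
#' `out[i, j, ] = c(f[i, ], f[j, ])`, joining the information of every pair
#' of positions.
#'
#' @param f numeric matrix `L x C`.
#' @return numeric array `L x L x 2C`.
#' @export
outer_concat <- function(f) {
  L <- nrow(f); C <- ncol(f)
  out <- array(0, c(L, L, 2L * C))
  for (c in seq_len(C)) {
    out[, , c] <- matrix(f[, c], L, L)               # row feature f[i, c]
    out[, , C + c] <- matrix(f[, c], L, L, byrow = TRUE)  # col feature f[j, c]
  }
  out
}

outer_concat_bwd <- function(dout) {
  L <- dim(dout)[1]; C <- dim(dout)[3] %/% 2L
  df <- matrix(0, L, C)
  for (c in seq_len(C)) {
    df[, c] <- rowSums(dout[, , c]) + colSums(dout[, , C + c])
  }
  df
}

# stochastic gradient descent with momentum and weight decay over flat
# named parameter lists; `frozen` is a vector of name prefixes
sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 0, frozen = character()) {
  for (nm in names(grads)) {
    if (length(frozen) && any(startsWith(nm, frozen))) next
    g <- grads[[nm]] + weight_decay * params[[nm]]
    v <- if (!is.null(state[[nm]])) state[[nm]] else 0
    v <- momentum * v - lr * g
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, state = state)
}

# elementwise sum of two flat gradient lists
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# max pooling over non-overlapping windows; cache records the argmax so the
# backward routes the gradient to the selected position only
maxpool1d_fwd <- function(x, f) {
  L <- nrow(x); C <- ncol(x)
  if (L %% f != 0) stop("pool factor must divide the length")
  Lo <- L %/% f
  y <- x[seq(1L, L, by = f), , drop = FALSE]
  am <- matrix(1L, Lo, C)
  if (f > 1L) for (o in 1:(f - 1L)) {
    cand <- x[seq(1L + o, L, by = f), , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    am[upd] <- o + 1L
  }
  list(y = y, cache = list(L = L, f = f, am = am))
}

maxpool1d_bwd <- function(dy, cache) {
  Lo <- nrow(dy); C <- ncol(dy)
  dx <- matrix(0, cache$L, C)
  rows <- (seq_len(Lo) - 1L) * cache$f + cache$am       # Lo x C row indices
  lin <- as.vector(rows) + rep((seq_len(C) - 1L) * cache$L, each = Lo)
  dx[lin] <- as.vector(dy)
  dx
}

pool1d_fwd <- function(x, f, type = c("avg", "max")) {
  type <- match.arg(type)
  out <- if (type == "avg") avgpool1d_fwd(x, f) else maxpool1d_fwd(x, f)
  out$cache$type <- type
  out
}

pool1d_bwd <- function(dy, cache) {
  if (identical(cache$type, "max")) maxpool1d_bwd(dy, cache)
  else avgpool1d_bwd(dy, cache)
}
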