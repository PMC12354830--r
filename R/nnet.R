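# Minimal CNN engine: im2col convolutions on top of BLAS gemm, batch
# normalization, dropout, max-pooling, dense layers, weighted binary
# cross-entropy and Adam. No deep-learning framework is assumed; the
# network is small (two conv blocks + one dense block) and the heavy
# lifting is three matrix products per batch.
#
# Layout conventions:
#   * spatial activation arrays are (H, W, N, C) -- batch before channels --
#     so that the (i, j, n) x channel matrix view used by im2col, batch
#     norm and the conv gemms is a plain dim<- reshape with no aperm copy;
#   * batch norm is column-wise over those channel-column matrices.

relu <- function(x) {
  d <- dim(x)
  x <- pmax.int(x, 0)
  dim(x) <- d
  x
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

# ---- im2col / col2im ----------------------------------------------------

# A: (H, W, N, C) array; k x k valid convolution patches.
# Returns (H2*W2*N) x (k*k*C) matrix; rows ordered (i, j, n), columns
# ordered channel-fastest within each (ki, kj) offset.
im2col <- function(A, k) {
  d <- dim(A)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  H2 <- H - k + 1L; W2 <- W - k + 1L
  M <- matrix(0, H2 * W2 * N, k * k * C)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      S <- A[ki:(ki + H2 - 1L), kj:(kj + W2 - 1L), , , drop = FALSE]
      dim(S) <- c(H2 * W2 * N, C)
      cols <- ((kj - 1L) * k + ki - 1L) * C + seq_len(C)
      M[, cols] <- S
    }
  }
  M
}

# Scatter-add transpose of im2col; dM as produced against an input of
# dimension dimA. Returns the gradient array of shape dimA.
col2im <- function(dM, dimA, k) {
  H <- dimA[1]; W <- dimA[2]; N <- dimA[3]; C <- dimA[4]
  H2 <- H - k + 1L; W2 <- W - k + 1L
  dA <- array(0, dimA)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      cols <- ((kj - 1L) * k + ki - 1L) * C + seq_len(C)
      P <- dM[, cols, drop = FALSE]
      dim(P) <- c(H2, W2, N, C)
      dA[ki:(ki + H2 - 1L), kj:(kj + W2 - 1L), , ] <-
        dA[ki:(ki + H2 - 1L), kj:(kj + W2 - 1L), , , drop = FALSE] + P
    }
  }
  dA
}

# matrix (rows (i,j,n) x C) -> array (H, W, N, C): a free reshape
mat_to_arr <- function(M, H, W, N) {
  dim(M) <- c(H, W, N, ncol(M))
  M
}

# array (H, W, N, C) -> matrix (rows (i,j,n) x C): a free reshape
arr_to_mat <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1] * d[2] * d[3], d[4])
  A
}

# ---- max pooling (2x2, stride 2, valid) --------------------------------

maxpool_forward <- function(A) {
  d <- dim(A)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  i1 <- seq(1L, 2L * H2, 2L); j1 <- seq(1L, 2L * W2, 2L)
  A11 <- A[i1, j1, , , drop = FALSE]
  A21 <- A[i1 + 1L, j1, , , drop = FALSE]
  A12 <- A[i1, j1 + 1L, , , drop = FALSE]
  A22 <- A[i1 + 1L, j1 + 1L, , , drop = FALSE]
  Y <- pmax(A11, A21, A12, A22)
  list(Y = Y, parts = list(A11, A21, A12, A22), dimA = d)
}

maxpool_backward <- function(cache, dY) {
  d <- cache$dimA
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  i1 <- seq(1L, 2L * H2, 2L); j1 <- seq(1L, 2L * W2, 2L)
  Y <- cache$Y
  dA <- array(0, d)
  taken <- array(FALSE, dim(Y))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (p in 1:4) {
    m <- (cache$parts[[p]] == Y) & !taken   # ties routed to first window cell
    taken <- taken | m
    o <- offs[[p]]
    dA[i1 + o[1], j1 + o[2], , ] <- m * dY
  }
  dA
}

# ---- batch normalization (column-wise over a features-in-columns matrix) --

bn_init <- function(nfeat) {
  list(gamma = rep(1, nfeat), beta = rep(0, nfeat),
       run_mean = rep(0, nfeat), run_var = rep(1, nfeat))
}

# y = X * a[col] + b[col], fused column-wise affine (avoids sweep(), which
# is slow on the ~100k-row conv activation matrices)
col_affine <- function(X, a, b) {
  m <- nrow(X)
  X * rep(a, each = m) + rep(b, each = m)
}

# y = X + b[col]
col_add <- function(X, b) {
  X + rep(b, each = nrow(X))
}

bn_forward <- function(X, p, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v[v < 0] <- 0
    istd <- 1 / sqrt(v + eps)
    xhat <- col_affine(X, istd, -mu * istd)
    p$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
    p$run_var <- momentum * p$run_var + (1 - momentum) * v
    Y <- col_affine(xhat, p$gamma, p$beta)
    list(Y = Y, p = p, cache = list(xhat = xhat, istd = istd))
  } else {
    istd <- 1 / sqrt(p$run_var + eps)
    Y <- col_affine(X, p$gamma * istd,
                    p$beta - p$run_mean * istd * p$gamma)
    list(Y = Y, p = p, cache = NULL)
  }
}

bn_backward <- function(dY, p, cache) {
  xhat <- cache$xhat
  m <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  # dxhat = dY * gamma; dX = istd * (dxhat - mean(dxhat) - xhat*mean(dxhat*xhat))
  g <- p$gamma
  s1 <- dbeta * g / m                 # colMeans(dxhat)
  s2 <- dgamma * g / m                # colMeans(dxhat * xhat)
  dX <- col_affine(dY, g * cache$istd, -s1 * cache$istd) -
    col_affine(xhat, s2 * cache$istd, rep(0, length(g)))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout ------------------------------------------------------------

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
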