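# From-scratch CNN + transformer network used by the scorer. Activations
# are stored sample-major: row (b-1)*L + l of an N x d matrix holds window
# position l of sample b, with N = batch * L. Forward and backward passes
# are plain matrix algebra; the only compiled piece is the block-diagonal
# batched product behind multi-head attention (src/blockmm.cpp).

#' Sinusoidal positional embeddings
#'
#' Standard base-10000 formulation: entry `(pos, 2i)` is
#' `sin(pos / 10000^(2i/d))` and entry `(pos, 2i+1)` the matching cosine,
#' with positions numbered from 0.
#'
#' @param n_positions Number of positions (rows).
#' @param d Even embedding dimension.
#' @return `n_positions x d` matrix with entries in `[-1, 1]`.
#' @export
sinusoidal_embedding <- function(n_positions, d) {
  if (d %% 2L != 0L) stop("sinusoidal_embedding: d must be even")
  if (n_positions < 1L) stop("sinusoidal_embedding: n_positions must be >= 1")
  pos <- 0:(n_positions - 1L)
  i <- 0:(d %/% 2L - 1L)
  ang <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, n_positions, d)
  pe[, 2L * i + 1L] <- sin(ang)
  pe[, 2L * i + 2L] <- cos(ang)
  pe
}

addb <- function(M, b) M + rep(b, rep.int(nrow(M), length(b)))

relu <- function(x) x * (x > 0)

# GELU via the fast sigmoid approximation x * sigmoid(1.702 x)
gelu_sig <- function(x) 1 / (1 + exp(-1.702 * x))
gelu <- function(x) x * gelu_sig(x)
dgelu <- function(x) {
  s <- gelu_sig(x)
  s + 1.702 * x * s * (1 - s)
}

# ---- parameter initialisation -------------------------------------------

he_mat <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)

init_params <- function(cfg) {
  p <- list()
  cin <- cfg$channels
  for (i in seq_len(cfg$n_conv)) {
    p[[sprintf("conv%d.W", i)]] <- he_mat(cfg$kernel * cin, cfg$filters)
    p[[sprintf("conv%d.b", i)]] <- numeric(cfg$filters)
    if (i < cfg$n_conv) {
      p[[sprintf("bn%d.gamma", i)]] <- rep(1, cfg$filters)
      p[[sprintf("bn%d.beta", i)]] <- numeric(cfg$filters)
    }
    cin <- cfg$filters
  }
  d <- cfg$filters
  for (t in seq_len(cfg$n_transformer)) {
    for (w in c("Wq", "Wk", "Wv", "Wo"))
      p[[sprintf("tr%d.%s", t, w)]] <- he_mat(d, d)
    for (b in c("bq", "bk", "bv", "bo"))
      p[[sprintf("tr%d.%s", t, b)]] <- numeric(d)
    p[[sprintf("tr%d.ln1.g", t)]] <- rep(1, d)
    p[[sprintf("tr%d.ln1.b", t)]] <- numeric(d)
    p[[sprintf("tr%d.W1", t)]] <- he_mat(d, cfg$ff_dim)
    p[[sprintf("tr%d.b1", t)]] <- numeric(cfg$ff_dim)
    p[[sprintf("tr%d.W2", t)]] <- he_mat(cfg$ff_dim, d)
    p[[sprintf("tr%d.b2", t)]] <- numeric(d)
    p[[sprintf("tr%d.ln2.g", t)]] <- rep(1, d)
    p[[sprintf("tr%d.ln2.b", t)]] <- numeric(d)
  }
  p[["head.Wf"]] <- he_mat(cfg$width * d, cfg$fc_units)
  p[["head.bf"]] <- numeric(cfg$fc_units)
  p[["head.Wout"]] <- he_mat(cfg$fc_units, 2L)
  p[["head.bout"]] <- numeric(2L)
  p
}

init_bn_stats <- function(cfg) {
  s <- list()
  for (i in seq_len(cfg$n_conv - 1L))
    s[[sprintf("bn%d", i)]] <- list(mean = numeric(cfg$filters),
                                    var = rep(1, cfg$filters), n = 0L)
  s
}

# ---- conv / norm layers --------------------------------------------------

# gather the kernel-neighborhood of every row into column blocks; rows are
# l-fastest within a sample so shifts never cross sample boundaries
im2col <- function(A, L, kernel) {
  N <- nrow(A); C <- ncol(A)
  k2 <- (kernel - 1L) %/% 2L
  ls <- rep(seq_len(L), N %/% L)
  M <- matrix(0, N, kernel * C)
  for (j in seq_len(kernel)) {
    o <- j - 1L - k2
    valid <- which(ls + o >= 1L & ls + o <= L)
    M[valid, ((j - 1L) * C + 1L):(j * C)] <- A[valid + o, , drop = FALSE]
  }
  M
}

col2im <- function(dM, L, kernel, C) {
  N <- nrow(dM)
  k2 <- (kernel - 1L) %/% 2L
  ls <- rep(seq_len(L), N %/% L)
  dA <- matrix(0, N, C)
  for (j in seq_len(kernel)) {
    o <- j - 1L - k2
    valid <- which(ls + o >= 1L & ls + o <= L)
    dA[valid + o, ] <- dA[valid + o, , drop = FALSE] +
      dM[valid, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dA
}

BN_EPS <- 1e-5
LN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_forward <- function(Z, gamma, beta, stats, train) {
  if (train) {
    mu <- colMeans(Z)
    zc <- addb(Z, -mu)
    v <- colMeans(zc^2)
    stats$mean <- BN_MOMENTUM * stats$mean + (1 - BN_MOMENTUM) * mu
    stats$var <- BN_MOMENTUM * stats$var + (1 - BN_MOMENTUM) * v
    stats$n <- stats$n + 1L
  } else {
    mu <- stats$mean
    v <- stats$var
    zc <- addb(Z, -mu)
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- zc * rep(inv, each = nrow(Z))
  list(out = addb(xhat * rep(gamma, each = nrow(Z)), beta),
       cache = list(xhat = xhat, inv = inv, gamma = gamma), stats = stats)
}

bn_backward <- function(dout, cache) {
  n <- nrow(dout)
  dxhat <- dout * rep(cache$gamma, each = n)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  # compact form: dz = inv/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dz <- (dxhat - rep(s1 / n, each = n) - cache$xhat * rep(s2 / n, each = n)) *
    rep(cache$inv, each = n)
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

ln_forward <- function(Z, g, b) {
  mu <- rowMeans(Z)
  zc <- Z - mu
  v <- rowMeans(zc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- zc * inv
  list(out = addb(xhat * rep(g, each = nrow(Z)), b),
       cache = list(xhat = xhat, inv = inv, g = g))
}

ln_backward <- function(dout, cache) {
  n <- nrow(dout); d <- ncol(dout)
  dxhat <- dout * rep(cache$g, each = n)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dz <- (dxhat - s1 / d - cache$xhat * (s2 / d)) * cache$inv
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  e <- exp(S - m)
  e / rowSums(e)
}

drop_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  matrix((runif(n) >= p) / (1 - p), nrow = 1L)[1L, ]  # plain vector
}

# ---- full network --------------------------------------------------------

nn_forward <- function(params, cfg, X, train, bn_stats) {
  B <- dim(X)[1L]; L <- dim(X)[2L]
  A <- matrix(aperm(X, c(2L, 1L, 3L)), nrow = B * L)
  N <- nrow(A)
  cache <- list(B = B, L = L)
  for (i in seq_len(cfg$n_conv)) {
    M <- im2col(A, L, cfg$kernel)
    Z <- addb(M %*% params[[sprintf("conv%d.W", i)]], params[[sprintf("conv%d.b", i)]])
    R <- relu(Z)
    cache[[sprintf("conv%d", i)]] <- list(M = M, Z = Z, Cin = ncol(A))
    if (i < cfg$n_conv) {
      bk <- sprintf("bn%d", i)
      bn <- bn_forward(R, params[[paste0(bk, ".gamma")]], params[[paste0(bk, ".beta")]],
                       bn_stats[[bk]], train)
      bn_stats[[bk]] <- bn$stats
      cache[[bk]] <- bn$cache
      A <- bn$out
    } else A <- R
  }
  pe <- sinusoidal_embedding(L, cfg$filters)
  A <- A + pe[rep(seq_len(L), B), ]
  d <- cfg$filters
  dk <- d %/% cfg$n_heads
  for (t in seq_len(cfg$n_transformer)) {
    tk <- function(s) sprintf("tr%d.%s", t, s)
    inp <- A
    Q <- addb(inp %*% params[[tk("Wq")]], params[[tk("bq")]])
    K <- addb(inp %*% params[[tk("Wk")]], params[[tk("bk")]])
    V <- addb(inp %*% params[[tk("Wv")]], params[[tk("bv")]])
    O <- matrix(0, N, d)
    Ps <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- blockmm(Q[, cols, drop = FALSE], K[, cols, drop = FALSE], L, "nt") / sqrt(dk)
      P <- row_softmax(S)
      Ps[[h]] <- P
      O[, cols] <- blockmm(P, V[, cols, drop = FALSE], L, "nn")
    }
    att <- addb(O %*% params[[tk("Wo")]], params[[tk("bo")]])
    m1 <- if (train) drop_mask(length(att), cfg$dropout) else NULL
    if (!is.null(m1)) att <- att * m1
    l1 <- ln_forward(inp + att, params[[tk("ln1.g")]], params[[tk("ln1.b")]])
    A1 <- l1$out
    H0 <- addb(A1 %*% params[[tk("W1")]], params[[tk("b1")]])
    H <- gelu(H0)
    F2 <- addb(H %*% params[[tk("W2")]], params[[tk("b2")]])
    m2 <- if (train) drop_mask(length(F2), cfg$dropout) else NULL
    if (!is.null(m2)) F2 <- F2 * m2
    l2 <- ln_forward(A1 + F2, params[[tk("ln2.g")]], params[[tk("ln2.b")]])
    cache[[sprintf("tr%d", t)]] <- list(inp = inp, Q = Q, K = K, V = V, O = O,
                                        Ps = Ps, m1 = m1, l1 = l1$cache, A1 = A1,
                                        H0 = H0, H = H, m2 = m2, l2 = l2$cache)
    A <- l2$out
  }
  A3 <- array(A, dim = c(L, B, d))
  Fm <- t(matrix(aperm(A3, c(1L, 3L, 2L)), nrow = L * d))
  H1 <- addb(Fm %*% params[["head.Wf"]], params[["head.bf"]])
  R1 <- relu(H1)
  logits <- addb(R1 %*% params[["head.Wout"]], params[["head.bout"]])
  probs <- row_softmax(logits)
  cache$head <- list(Fm = Fm, H1 = H1, R1 = R1)
  list(probs = probs, cache = cache, bn_stats = bn_stats)
}

# cross-entropy gradient through the whole stack; y in {0, 1}
nn_backward <- function(params, cfg, fw, y) {
  cache <- fw$cache
  B <- cache$B; L <- cache$L
  d <- cfg$filters; dk <- d %/% cfg$n_heads
  g <- list()
  Y <- cbind(1 - y, y, deparse.level = 0)
  dlogits <- (fw$probs - Y) / B
  hd <- cache$head
  g[["head.Wout"]] <- crossprod(hd$R1, dlogits)
  g[["head.bout"]] <- colSums(dlogits)
  dR1 <- tcrossprod(dlogits, params[["head.Wout"]])
  dH1 <- dR1 * (hd$H1 > 0)
  g[["head.Wf"]] <- crossprod(hd$Fm, dH1)
  g[["head.bf"]] <- colSums(dH1)
  dFm <- tcrossprod(dH1, params[["head.Wf"]])
  dA <- matrix(aperm(array(t(dFm), dim = c(L, d, B)), c(1L, 3L, 2L)), nrow = B * L)
  for (t in rev(seq_len(cfg$n_transformer))) {
    tk <- function(s) sprintf("tr%d.%s", t, s)
    cc <- cache[[sprintf("tr%d", t)]]
    lb2 <- ln_backward(dA, cc$l2)
    g[[tk("ln2.g")]] <- lb2$dgamma; g[[tk("ln2.b")]] <- lb2$dbeta
    dres2 <- lb2$dz
    dF2 <- if (is.null(cc$m2)) dres2 else dres2 * cc$m2
    dA1 <- dres2
    g[[tk("W2")]] <- crossprod(cc$H, dF2)
    g[[tk("b2")]] <- colSums(dF2)
    dH <- tcrossprod(dF2, params[[tk("W2")]])
    dH0 <- dH * dgelu(cc$H0)
    g[[tk("W1")]] <- crossprod(cc$A1, dH0)
    g[[tk("b1")]] <- colSums(dH0)
    dA1 <- dA1 + tcrossprod(dH0, params[[tk("W1")]])
    lb1 <- ln_backward(dA1, cc$l1)
    g[[tk("ln1.g")]] <- lb1$dgamma; g[[tk("ln1.b")]] <- lb1$dbeta
    dres1 <- lb1$dz
    datt <- if (is.null(cc$m1)) dres1 else dres1 * cc$m1
    dinp <- dres1
    g[[tk("Wo")]] <- crossprod(cc$O, datt)
    g[[tk("bo")]] <- colSums(datt)
    dO <- tcrossprod(datt, params[[tk("Wo")]])
    dQ <- matrix(0, nrow(dO), d); dK <- dQ; dV <- dQ
    for (h in seq_len(cfg$n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      P <- cc$Ps[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dP <- blockmm(dOh, cc$V[, cols, drop = FALSE], L, "nt")
      dV[, cols] <- blockmm(P, dOh, L, "tn")
      dS <- P * (dP - rowSums(dP * P))
      dS <- dS / sqrt(dk)
      dQ[, cols] <- blockmm(dS, cc$K[, cols, drop = FALSE], L, "nn")
      dK[, cols] <- blockmm(dS, cc$Q[, cols, drop = FALSE], L, "tn")
    }
    g[[tk("Wq")]] <- crossprod(cc$inp, dQ); g[[tk("bq")]] <- colSums(dQ)
    g[[tk("Wk")]] <- crossprod(cc$inp, dK); g[[tk("bk")]] <- colSums(dK)
    g[[tk("Wv")]] <- crossprod(cc$inp, dV); g[[tk("bv")]] <- colSums(dV)
    dA <- dinp + dQ %*% t(params[[tk("Wq")]]) + dK %*% t(params[[tk("Wk")]]) +
      dV %*% t(params[[tk("Wv")]])
  }
  for (i in rev(seq_len(cfg$n_conv))) {
    cc <- cache[[sprintf("conv%d", i)]]
    if (i < cfg$n_conv) {
      bk <- sprintf("bn%d", i)
      bb <- bn_backward(dA, cache[[bk]])
      g[[paste0(bk, ".gamma")]] <- bb$dgamma
      g[[paste0(bk, ".beta")]] <- bb$dbeta
      dA <- bb$dz
    }
    dZ <- dA * (cc$Z > 0)
    g[[sprintf("conv%d.W", i)]] <- crossprod(cc$M, dZ)
    g[[sprintf("conv%d.b", i)]] <- colSums(dZ)
    dM <- tcrossprod(dZ, params[[sprintf("conv%d.W", i)]])
    dA <- col2im(dM, L, cfg$kernel, cc$Cin)
  }
  g
}

ce_loss <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    gn <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gn
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gn^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}
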