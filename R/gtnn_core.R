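# GTNN numerical core: batched forward pass with caches and the matching
# manual backward pass.  Graphs in a batch are stacked into one node set with
# a per-node graph index; neighbor sums and attention normalizers use
# grouped row sums, so everything is permutation invariant by construction.

relu <- function(x) x * (x > 0)

# affine map with a cheap bias broadcast (avoids sweep's aperm copies)
lin <- function(X, W, b) X %*% W + rep(b, each = nrow(X))

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -35), 35)))

# grouped row sum with a fixed number of groups (empty groups -> zero rows)
rowsum_n <- function(x, group, n) {
  rs <- rowsum(x, group)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

addm <- function(container, name, value) {
  if (is.null(container[[name]])) container[[name]] <- value
  else container[[name]] <- container[[name]] + value
  container
}

#' Apply one message-passing layer
#'
#' Computes `phi(h_i, sum_{j in N(i)} psi(h_i, h_j[, r_ij]))` for every atom:
#' messages from each neighbor are produced by the two-layer MLP `psi`,
#' aggregated by the permutation-invariant sum (an atom without neighbors
#' receives the zero vector), and combined with the receiving atom's state by
#' the two-layer MLP `phi`.
#'
#' @param features n x d matrix of atom representations.
#' @param edges m x 2 matrix of undirected 1-based atom index pairs.
#' @param weights named list `psi_W1` ((2d + r) x u), `psi_b1`, `psi_W2`
#'   (u x d), `psi_b2`, `phi_W1` (2d x u), `phi_b1`, `phi_W2` (u x d),
#'   `phi_b2`.
#' @param distances optional m x r matrix of edge distance features (3D
#'   mode), one row per undirected edge.
#' @param residual add the input features to the update (the in-model
#'   default); the plain form returns `phi(...)` alone.
#' @return n x d matrix of updated atom representations.
#' @export
message_passing_layer <- function(features, edges, weights, distances = NULL,
                                  residual = FALSE) {
  n <- nrow(features)
  if (length(edges) > 0L && max(edges) > n) {
    stop_mf("shape_error", "edge index exceeds atom count")
  }
  if (nrow(features) == 0L) stop_mf("empty_input_error", "no atoms")
  d <- ncol(features)
  if (nrow(weights$psi_W1) != 2L * d + (if (is.null(distances)) 0L else ncol(distances))) {
    stop_mf("shape_error", "psi_W1 input dimension mismatch")
  }
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  R <- if (!is.null(distances)) rbind(distances, distances) else NULL
  out <- mp_forward(features, src, dst, R, weights, residual = residual)
  out$H
}

mp_forward <- function(H, src, dst, R, w, residual = TRUE) {
  n <- nrow(H)
  if (length(src) > 0L) {
    Min <- cbind(H[src, , drop = FALSE], H[dst, , drop = FALSE])
    if (!is.null(R)) Min <- cbind(Min, R)
    Z1 <- lin(Min, w$psi_W1, w$psi_b1)
    A1 <- relu(Z1)
    M <- lin(A1, w$psi_W2, w$psi_b2)
    S <- rowsum_n(M, src, n)
  } else {
    Min <- NULL; Z1 <- NULL; A1 <- NULL; M <- NULL
    S <- matrix(0, n, ncol(w$psi_W2))
  }
  U <- cbind(H, S)
  Z2 <- lin(U, w$phi_W1, w$phi_b1)
  A2 <- relu(Z2)
  D <- lin(A2, w$phi_W2, w$phi_b2)
  Hn <- if (residual) H + D else D
  list(H = Hn, cache = list(Min = Min, A1 = A1, U = U, A2 = A2,
                            src = src, dst = dst, n = n,
                            residual = residual))
}

mp_backward <- function(dHn, cache, w) {
  # returns list(dH, grads = list(psi_W1, psi_b1, psi_W2, psi_b2, phi_*))
  dD <- dHn
  dA2 <- tcrossprod(dD, w$phi_W2)
  g_phi_W2 <- crossprod(cache$A2, dD)
  g_phi_b2 <- colSums(dD)
  dZ2 <- dA2 * (cache$A2 > 0)
  dU <- tcrossprod(dZ2, w$phi_W1)
  g_phi_W1 <- crossprod(cache$U, dZ2)
  g_phi_b1 <- colSums(dZ2)
  h <- ncol(dHn)
  dH <- dU[, seq_len(h), drop = FALSE]
  dS <- dU[, h + seq_len(ncol(dU) - h), drop = FALSE]
  if (cache$residual) dH <- dH + dHn

  if (length(cache$src) > 0L) {
    dM <- dS[cache$src, , drop = FALSE]
    dA1 <- tcrossprod(dM, w$psi_W2)
    g_psi_W2 <- crossprod(cache$A1, dM)
    g_psi_b2 <- colSums(dM)
    dZ1 <- dA1 * (cache$A1 > 0)
    dMin <- tcrossprod(dZ1, w$psi_W1)
    g_psi_W1 <- crossprod(cache$Min, dZ1)
    g_psi_b1 <- colSums(dZ1)
    dH <- dH + rowsum_n(dMin[, seq_len(h), drop = FALSE], cache$src, cache$n) +
      rowsum_n(dMin[, h + seq_len(h), drop = FALSE], cache$dst, cache$n)
  } else {
    g_psi_W1 <- 0 * w$psi_W1; g_psi_b1 <- 0 * w$psi_b1
    g_psi_W2 <- 0 * w$psi_W2; g_psi_b2 <- 0 * w$psi_b2
  }
  list(dH = dH,
       grads = list(psi_W1 = g_psi_W1, psi_b1 = g_psi_b1,
                    psi_W2 = g_psi_W2, psi_b2 = g_psi_b2,
                    phi_W1 = g_phi_W1, phi_b1 = g_phi_b1,
                    phi_W2 = g_phi_W2, phi_b2 = g_phi_b2))
}

layer_weights <- function(P, t, l) {
  list(psi_W1 = P[[sprintf("%s.psi%d.W1", t, l)]],
       psi_b1 = P[[sprintf("%s.psi%d.b1", t, l)]],
       psi_W2 = P[[sprintf("%s.psi%d.W2", t, l)]],
       psi_b2 = P[[sprintf("%s.psi%d.b2", t, l)]],
       phi_W1 = P[[sprintf("%s.phi%d.W1", t, l)]],
       phi_b1 = P[[sprintf("%s.phi%d.b1", t, l)]],
       phi_W2 = P[[sprintf("%s.phi%d.W2", t, l)]],
       phi_b2 = P[[sprintf("%s.phi%d.b2", t, l)]])
}

CLAMP <- 30

# tower forward: X (N x 20), directed src/dst, R (directed-edge distance
# features or NULL), gid (graph index per node), G graphs
tower_forward <- function(P, cfg, t, X, src, dst, R, gid, G) {
  A_emb <- relu(lin(X, P$emb.W1, P$emb.b1))
  H0 <- relu(lin(A_emb, P$emb.W2, P$emb.b2))
  Hs <- vector("list", cfg$n_layers)
  caches <- vector("list", cfg$n_layers)
  H <- H0
  for (l in seq_len(cfg$n_layers)) {
    out <- mp_forward(H, src, dst, R, layer_weights(P, t, l), residual = TRUE)
    H <- out$H
    Hs[[l]] <- H
    caches[[l]] <- out$cache
  }
  Hcat <- do.call(cbind, Hs)
  A1f <- relu(lin(Hcat, P[[paste0(t, ".fin.W1")]], P[[paste0(t, ".fin.b1")]]))
  Ffin <- lin(A1f, P[[paste0(t, ".fin.W2")]], P[[paste0(t, ".fin.b2")]])

  # attention pooling with learnable seed queries
  h <- cfg$hidden_dim
  K <- lin(Ffin, P[[paste0(t, ".pool.Wk")]], P[[paste0(t, ".pool.bk")]])
  V <- lin(Ffin, P[[paste0(t, ".pool.Wv")]], P[[paste0(t, ".pool.bv")]])
  Q <- lin(P[[paste0(t, ".pool.S")]], P[[paste0(t, ".pool.Wq")]],
           P[[paste0(t, ".pool.bq")]])
  Sc_raw <- K %*% t(Q) / sqrt(h)
  mask <- abs(Sc_raw) < CLAMP
  Sc <- pmin(pmax(Sc_raw, -CLAMP), CLAMP)
  Eexp <- exp(Sc)
  Den <- rowsum_n(Eexp, gid, G)
  Attn <- Eexp / Den[gid, , drop = FALSE]
  heads <- cfg$pool_heads
  Pheads <- vector("list", heads)
  for (k in seq_len(heads)) {
    Pheads[[k]] <- rowsum_n(V * Attn[, k], gid, G)
  }
  Pcat <- do.call(cbind, Pheads)
  Pm <- lin(Pcat, P[[paste0(t, ".pool.Wo")]], P[[paste0(t, ".pool.bo")]])

  list(Pm = Pm,
       cache = list(X = X, A_emb = A_emb, H0 = H0, Hs = Hs, caches = caches,
                    Hcat = Hcat, A1f = A1f, Ffin = Ffin, K = K, V = V, Q = Q,
                    mask = mask, Attn = Attn, Pcat = Pcat, gid = gid, G = G,
                    src = src, dst = dst))
}

tower_backward <- function(P, cfg, t, dPm, cache, grads) {
  h <- cfg$hidden_dim
  heads <- cfg$pool_heads
  gid <- cache$gid; G <- cache$G
  N <- nrow(cache$Ffin)

  grads <- addm(grads, paste0(t, ".pool.Wo"), crossprod(cache$Pcat, dPm))
  grads <- addm(grads, paste0(t, ".pool.bo"), colSums(dPm))
  dPcat <- tcrossprod(dPm, P[[paste0(t, ".pool.Wo")]])

  dV <- matrix(0, N, h)
  dAttn <- matrix(0, N, heads)
  for (k in seq_len(heads)) {
    dPk <- dPcat[, (k - 1L) * h + seq_len(h), drop = FALSE]
    dPk_nodes <- dPk[gid, , drop = FALSE]
    dV <- dV + dPk_nodes * cache$Attn[, k]
    dAttn[, k] <- rowSums(cache$V * dPk_nodes)
  }
  # softmax (grouped) backward
  Tg <- rowsum_n(cache$Attn * dAttn, gid, G)
  dSc <- cache$Attn * (dAttn - Tg[gid, , drop = FALSE])
  dSc[!cache$mask] <- 0

  dK <- dSc %*% cache$Q / sqrt(h)
  dQ <- crossprod(dSc, cache$K) / sqrt(h)
  grads <- addm(grads, paste0(t, ".pool.bq"), colSums(dQ))
  grads <- addm(grads, paste0(t, ".pool.Wq"),
                crossprod(P[[paste0(t, ".pool.S")]], dQ))
  grads <- addm(grads, paste0(t, ".pool.S"),
                tcrossprod(dQ, P[[paste0(t, ".pool.Wq")]]))
  grads <- addm(grads, paste0(t, ".pool.Wk"), crossprod(cache$Ffin, dK))
  grads <- addm(grads, paste0(t, ".pool.bk"), colSums(dK))
  grads <- addm(grads, paste0(t, ".pool.Wv"), crossprod(cache$Ffin, dV))
  grads <- addm(grads, paste0(t, ".pool.bv"), colSums(dV))
  dF <- tcrossprod(dK, P[[paste0(t, ".pool.Wk")]]) +
    tcrossprod(dV, P[[paste0(t, ".pool.Wv")]])

  grads <- addm(grads, paste0(t, ".fin.W2"), crossprod(cache$A1f, dF))
  grads <- addm(grads, paste0(t, ".fin.b2"), colSums(dF))
  dA1f <- tcrossprod(dF, P[[paste0(t, ".fin.W2")]])
  dZ1f <- dA1f * (cache$A1f > 0)
  grads <- addm(grads, paste0(t, ".fin.W1"), crossprod(cache$Hcat, dZ1f))
  grads <- addm(grads, paste0(t, ".fin.b1"), colSums(dZ1f))
  dHcat <- tcrossprod(dZ1f, P[[paste0(t, ".fin.W1")]])

  L <- cfg$n_layers
  dH_next <- matrix(0, N, h)
  for (l in rev(seq_len(L))) {
    dHl <- dH_next + dHcat[, (l - 1L) * h + seq_len(h), drop = FALSE]
    bk <- mp_backward(dHl, cache$caches[[l]], layer_weights(P, t, l))
    for (nm in names(bk$grads)) {
      pm <- sub("_", sprintf("%d.", l), nm)  # psi_W1 -> psi1.W1
      grads <- addm(grads, sprintf("%s.%s", t, pm), bk$grads[[nm]])
    }
    dH_next <- bk$dH
  }
  dH0 <- dH_next

  dZe2 <- dH0 * (cache$H0 > 0)
  grads <- addm(grads, "emb.W2", crossprod(cache$A_emb, dZe2))
  grads <- addm(grads, "emb.b2", colSums(dZe2))
  dAe <- tcrossprod(dZe2, P$emb.W2)
  dZe1 <- dAe * (cache$A_emb > 0)
  grads <- addm(grads, "emb.W1", crossprod(cache$X, dZe1))
  grads <- addm(grads, "emb.b1", colSums(dZe1))
  grads
}

# full-model batched forward; batch: list(ar = list(X, src, dst, R, gid),
# ac = ..., C = G x n_cond condition matrix)
gtnn_forward <- function(P, cfg, batch) {
  mapa <- batch$ar$map
  mapb <- batch$ac$map
  ta <- tower_forward(P, cfg, "ar", batch$ar$X, batch$ar$src, batch$ar$dst,
                      batch$ar$R, batch$ar$gid, max(mapa))
  tb <- tower_forward(P, cfg, "ac", batch$ac$X, batch$ac$src, batch$ac$dst,
                      batch$ac$R, batch$ac$gid, max(mapb))
  Ce <- lin(batch$C, P$cond.W, P$cond.b)
  Zc <- cbind(ta$Pm[mapa, , drop = FALSE], tb$Pm[mapb, , drop = FALSE], Ce)
  T1 <- relu(lin(Zc, P$head.W1, P$head.b1))
  T2 <- relu(lin(T1, P$head.W2, P$head.b2))
  logit <- lin(T2, P$head.W3, P$head.b3)
  y <- sigmoid(logit)
  list(y = drop(y),
       cache = list(ta = ta, tb = tb, Zc = Zc, T1 = T1, T2 = T2, y = y))
}

gtnn_backward <- function(P, cfg, batch, fwd, dy) {
  cache <- fwd$cache
  grads <- list()
  y <- cache$y
  dlogit <- matrix(dy * y * (1 - y), ncol = 1)

  grads <- addm(grads, "head.W3", crossprod(cache$T2, dlogit))
  grads <- addm(grads, "head.b3", colSums(dlogit))
  dT2 <- tcrossprod(dlogit, P$head.W3) * (cache$T2 > 0)
  grads <- addm(grads, "head.W2", crossprod(cache$T1, dT2))
  grads <- addm(grads, "head.b2", colSums(dT2))
  dT1 <- tcrossprod(dT2, P$head.W2) * (cache$T1 > 0)
  grads <- addm(grads, "head.W1", crossprod(cache$Zc, dT1))
  grads <- addm(grads, "head.b1", colSums(dT1))
  dZc <- tcrossprod(dT1, P$head.W1)

  e <- cfg$embed_dim
  dPa <- rowsum_n(dZc[, seq_len(e), drop = FALSE], batch$ar$map,
                  max(batch$ar$map))
  dPb <- rowsum_n(dZc[, e + seq_len(e), drop = FALSE], batch$ac$map,
                  max(batch$ac$map))
  dCe <- dZc[, 2L * e + seq_len(e), drop = FALSE]
  grads <- addm(grads, "cond.W", crossprod(batch$C, dCe))
  grads <- addm(grads, "cond.b", colSums(dCe))

  grads <- tower_backward(P, cfg, "ar", dPa, cache$ta$cache, grads)
  grads <- tower_backward(P, cfg, "ac", dPb, cache$tb$cache, grads)
  grads
}

# Adam optimizer on the flattened parameter vector (one vectorized update
# per step instead of one per weight matrix)
flatten_params <- function(P) unlist(P, use.names = FALSE)

unflatten_params <- function(theta, template) {
  off <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    template[[nm]][] <- theta[off + seq_len(len)]
    off <- off + len
  }
  template
}

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step_flat <- function(theta, gvec, state, lr, weight_decay = 0,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gvec
  state$v <- beta2 * state$v + (1 - beta2) * gvec * gvec
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mh / (sqrt(vh) + eps)
  if (weight_decay > 0) theta <- theta - lr * weight_decay * theta
  list(theta = theta, state = state)
}
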