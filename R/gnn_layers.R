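# The four message-passing layers. Forward passes follow the operator
# definitions exactly; backward passes are hand-derived and verified
# against finite differences in the test suite.
#
#   GCN : h_i' = sigma( sum_{j in N(i) u {i}} (dhat_i dhat_j)^{-1/2} W h_j )
#         with dhat_i = 1 + sum_j e_{j,i} (edge weights default 1)
#   GAT : h_i' = sigma( sum_{j in N(i) u {i}} alpha_ij W h_j ),
#         alpha_ij = softmax_j LeakyReLU( a^T [W h_i || W h_j] )
#   SAGE: h_i' = sigma( W1 h_i + W2 mean_{j in N(i)} h_j )
#   GIN : h_i' = MLP( (1 + eps) h_i + sum_{j in N(i)} h_j )
#
# All layers operate on a batch topology: `arcs` is an A x 2 matrix of
# (source, target) node indices containing both directions of every bond
# and no self-arcs; self-loops are added internally where the operator
# includes them. Neighbourhood aggregation is weighted gather/scatter via
# base R's grouped `rowsum`, which keeps the hot path free of method
# dispatch on graphs this small.

relu <- function(x) pmax(x, 0)
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# Group sums with a guaranteed row (zero-filled) for every node 1..n.
rowsum_matrix <- function(x, index, n) {
  rs <- rowsum(x, group = index)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

rowsum_vector <- function(x, index, n) {
  rs <- rowsum(x, group = index)
  out <- numeric(n)
  out[as.integer(rownames(rs))] <- rs
  out
}

# y_i = sum_k w_k x_{src_k} over arcs with dst_k = i
aggregate_arcs <- function(X, src, dst, w, n) {
  rowsum_matrix(w * X[src, , drop = FALSE], dst, n)
}

# Batch topology: precomputed weighted arc lists shared by the layer stack.
build_topology <- function(n_nodes, arcs, edge_weight = NULL) {
  A <- nrow(arcs)
  w <- if (is.null(edge_weight)) rep(1, A) else edge_weight
  stopifnot(length(w) == A)
  src <- arcs[, 1]
  dst <- arcs[, 2]
  deg_in <- rowsum_vector(w, dst, n_nodes)          # incoming edge weights
  dhat <- 1 + deg_in                                 # self-loop included
  # GCN operator: arcs plus self-loops, coefficient (dhat_i dhat_j)^{-1/2}
  gcn_src <- c(src, seq_len(n_nodes))
  gcn_dst <- c(dst, seq_len(n_nodes))
  gcn_w <- c(w / sqrt(dhat[dst] * dhat[src]), 1 / dhat)
  # mean aggregation (no self-loop); isolated nodes contribute zero
  nnb <- rowsum_vector(rep(1, A), dst, n_nodes)
  mean_w <- 1 / pmax(nnb[dst], 1)
  list(n_nodes = n_nodes, arcs = arcs, edge_weight = w,
       src = src, dst = dst, dhat = dhat,
       gcn_src = gcn_src, gcn_dst = gcn_dst, gcn_w = gcn_w,
       mean_w = mean_w)
}

# ---------------------------------------------------------------- GCN ----

gcn_forward <- function(H, topo, params, activation = TRUE) {
  HW <- H %*% t(params$W)
  Z <- aggregate_arcs(HW, topo$gcn_src, topo$gcn_dst, topo$gcn_w,
                      topo$n_nodes)
  Hn <- if (activation) relu(Z) else Z
  list(H = Hn, cache = list(H = H, Z = Z, activation = activation))
}

gcn_backward <- function(dH, cache, topo, params) {
  dZ <- if (cache$activation) dH * (cache$Z > 0) else dH
  # transpose of the aggregation swaps source and target
  dHW <- aggregate_arcs(dZ, topo$gcn_dst, topo$gcn_src, topo$gcn_w,
                        topo$n_nodes)
  dW <- t(dHW) %*% cache$H
  dHin <- dHW %*% params$W
  list(grads = list(W = dW), dH = dHin)
}

# ---------------------------------------------------------------- GAT ----

gat_forward <- function(H, topo, params, activation = TRUE,
                        slope = 0.2, edge_attr = NULL) {
  n <- nrow(H)
  WH <- H %*% t(params$W)                    # n x out
  out <- ncol(WH)
  src <- c(topo$src, seq_len(n))             # self-loops appended
  dst <- c(topo$dst, seq_len(n))
  a_i <- params$a[seq_len(out)]
  a_j <- params$a[out + seq_len(out)]
  q <- as.numeric(WH[dst, , drop = FALSE] %*% a_i +
                  WH[src, , drop = FALSE] %*% a_j)
  e_feat <- NULL
  if (!is.null(edge_attr) && length(params$a) > 2 * out) {
    a_e <- params$a[(2 * out + 1):length(params$a)]
    e_feat <- rbind(edge_attr, matrix(0, n, ncol(edge_attr)))
    q <- q + as.numeric(e_feat %*% a_e)
  }
  l <- leaky_relu(q, slope)
  grp <- factor(dst, levels = seq_len(n))
  mx <- unname(vapply(split(l, grp),
                      function(v) if (length(v)) max(v) else 0, 0)[dst])
  ex <- exp(l - mx)
  alpha <- ex / rowsum_vector(ex, dst, n)[dst]
  Z <- aggregate_arcs(WH, src, dst, alpha, n)
  Hn <- if (activation) relu(Z) else Z
  list(H = Hn, alpha = alpha, arcs_sl = cbind(src, dst),
       cache = list(WH = WH, src = src, dst = dst, q = q, alpha = alpha,
                    Z = Z, slope = slope, activation = activation,
                    e_feat = e_feat, H = H))
}

gat_backward <- function(dH, cache, topo, params) {
  src <- cache$src; dst <- cache$dst
  WH <- cache$WH; alpha <- cache$alpha
  n <- nrow(WH); out <- ncol(WH)
  dZ <- if (cache$activation) dH * (cache$Z > 0) else dH

  dalpha <- rowSums(dZ[dst, , drop = FALSE] * WH[src, , drop = FALSE])
  # message term: d WH[src] += alpha * dZ[dst]
  dWH <- aggregate_arcs(dZ, dst, src, alpha, n)

  Ssum <- rowsum_vector(alpha * dalpha, dst, n)[dst]
  dl <- alpha * (dalpha - Ssum)
  dq <- dl * ifelse(cache$q > 0, 1, cache$slope)

  a_i <- params$a[seq_len(out)]
  a_j <- params$a[out + seq_len(out)]
  da <- c(colSums(dq * WH[dst, , drop = FALSE]),
          colSums(dq * WH[src, , drop = FALSE]))
  if (!is.null(cache$e_feat)) {
    da <- c(da, colSums(dq * cache$e_feat))
  }
  dWH <- dWH + rowsum_matrix(dq %o% a_i, dst, n) +
    rowsum_matrix(dq %o% a_j, src, n)

  dW <- t(dWH) %*% cache$H
  dHin <- dWH %*% params$W
  list(grads = list(W = dW, a = da), dH = dHin)
}

# --------------------------------------------------------------- SAGE ----

sage_forward <- function(H, topo, params, activation = TRUE) {
  MH <- aggregate_arcs(H, topo$src, topo$dst, topo$mean_w, topo$n_nodes)
  Z <- H %*% t(params$W1) + MH %*% t(params$W2)
  Hn <- if (activation) relu(Z) else Z
  list(H = Hn, cache = list(MH = MH, Z = Z, H = H, activation = activation))
}

sage_backward <- function(dH, cache, topo, params) {
  dZ <- if (cache$activation) dH * (cache$Z > 0) else dH
  dW1 <- t(dZ) %*% cache$H
  dW2 <- t(dZ) %*% cache$MH
  dHin <- dZ %*% params$W1 +
    aggregate_arcs(dZ %*% params$W2, topo$dst, topo$src, topo$mean_w,
                   topo$n_nodes)
  list(grads = list(W1 = dW1, W2 = dW2), dH = dHin)
}

# ---------------------------------------------------------------- GIN ----

gin_forward <- function(H, topo, params, activation = TRUE) {
  AH <- aggregate_arcs(H, topo$src, topo$dst, rep(1, length(topo$src)),
                       topo$n_nodes)
  P <- (1 + params$eps) * H + AH
  Z1 <- P %*% t(params$U1) + matrix(params$b1, nrow(H), length(params$b1),
                                    byrow = TRUE)
  R <- relu(Z1)
  Z2 <- R %*% t(params$U2) + matrix(params$b2, nrow(H), length(params$b2),
                                    byrow = TRUE)
  Hn <- if (activation) relu(Z2) else Z2
  list(H = Hn, cache = list(P = P, Z1 = Z1, R = R, Z2 = Z2, H = H,
                            activation = activation))
}

gin_backward <- function(dH, cache, topo, params) {
  dZ2 <- if (cache$activation) dH * (cache$Z2 > 0) else dH
  dU2 <- t(dZ2) %*% cache$R
  db2 <- colSums(dZ2)
  dR <- dZ2 %*% params$U2
  dZ1 <- dR * (cache$Z1 > 0)
  dU1 <- t(dZ1) %*% cache$P
  db1 <- colSums(dZ1)
  dP <- dZ1 %*% params$U1
  dHin <- (1 + params$eps) * dP +
    aggregate_arcs(dP, topo$dst, topo$src, rep(1, length(topo$src)),
                   topo$n_nodes)
  list(grads = list(U1 = dU1, b1 = db1, U2 = dU2, b2 = db2), dH = dHin)
}

layer_forward <- function(conv_type, H, topo, params, activation = TRUE,
                          edge_attr = NULL) {
  switch(conv_type,
         gcn = gcn_forward(H, topo, params, activation),
         gat = gat_forward(H, topo, params, activation, edge_attr = edge_attr),
         sage = sage_forward(H, topo, params, activation),
         gin = gin_forward(H, topo, params, activation),
         stop("unknown conv_type: ", conv_type))
}

layer_backward <- function(conv_type, dH, cache, topo, params) {
  switch(conv_type,
         gcn = gcn_backward(dH, cache, topo, params),
         gat = gat_backward(dH, cache, topo, params),
         sage = sage_backward(dH, cache, topo, params),
         gin = gin_backward(dH, cache, topo, params),
         stop("unknown conv_type: ", conv_type))
}
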