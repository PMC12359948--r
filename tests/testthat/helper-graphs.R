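# In-code fixtures: random graph builders and independent per-node loop
# oracles for the four message-passing layers. The oracles deliberately
# avoid the package's sparse-matrix code path.

ns <- asNamespace("molgraphnn")

random_arcs <- function(n, p = 0.5) {
  arcs <- matrix(integer(), 0, 2)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) arcs <- rbind(arcs, c(i, j), c(j, i))
      }
    }
  }
  arcs
}

random_molecular_graph <- function(n, d, d_edge = 2L, label = 1L, p = 0.5) {
  arcs <- random_arcs(n, p)
  structure(list(graph_id = sprintf("rg%06d", sample.int(1e6, 1)),
                 n_nodes = n,
                 node_matrix = matrix(stats::rnorm(n * d), n, d),
                 arcs = arcs,
                 edge_matrix = matrix(stats::rnorm(nrow(arcs) * d_edge),
                                      nrow(arcs), d_edge),
                 label = label),
            class = "molecular_graph")
}

neighbours_of <- function(arcs, i) arcs[arcs[, 2] == i, 1]

oracle_gcn <- function(X, arcs, W) {
  n <- nrow(X)
  H <- matrix(0, n, nrow(W))
  dhat <- vapply(seq_len(n), function(i) 1 + length(neighbours_of(arcs, i)), 0)
  for (i in seq_len(n)) {
    acc <- numeric(nrow(W))
    for (j in c(neighbours_of(arcs, i), i)) {
      acc <- acc + (1 / sqrt(dhat[i] * dhat[j])) * as.numeric(W %*% X[j, ])
    }
    H[i, ] <- acc
  }
  H
}

oracle_gat <- function(X, arcs, W, a, slope = 0.2) {
  n <- nrow(X)
  out <- nrow(W)
  WH <- X %*% t(W)
  lk <- function(x) ifelse(x > 0, x, slope * x)
  H <- matrix(0, n, out)
  for (i in seq_len(n)) {
    nb <- c(neighbours_of(arcs, i), i)
    logits <- vapply(nb, function(j) lk(sum(a * c(WH[i, ], WH[j, ]))), 0)
    al <- exp(logits - max(logits))
    al <- al / sum(al)
    H[i, ] <- colSums(al * WH[nb, , drop = FALSE])
  }
  H
}

oracle_sage <- function(X, arcs, W1, W2) {
  n <- nrow(X)
  H <- matrix(0, n, nrow(W1))
  for (i in seq_len(n)) {
    nb <- neighbours_of(arcs, i)
    mn <- if (length(nb)) colMeans(X[nb, , drop = FALSE]) else
      numeric(ncol(X))
    H[i, ] <- as.numeric(W1 %*% X[i, ]) + as.numeric(W2 %*% mn)
  }
  H
}

oracle_gin <- function(X, arcs, U1, b1, U2, b2, eps = 0) {
  n <- nrow(X)
  H <- matrix(0, n, nrow(U1))
  for (i in seq_len(n)) {
    nb <- neighbours_of(arcs, i)
    p <- (1 + eps) * X[i, ] +
      if (length(nb)) colSums(X[nb, , drop = FALSE]) else numeric(ncol(X))
    z1 <- as.numeric(U1 %*% p) + b1
    H[i, ] <- as.numeric(U2 %*% pmax(z1, 0)) + b2
  }
  H
}

random_layer_params <- function(conv_type, d_in, d_out) {
  switch(conv_type,
         gcn = list(W = matrix(stats::rnorm(d_out * d_in), d_out, d_in)),
         gat = list(W = matrix(stats::rnorm(d_out * d_in), d_out, d_in),
                    a = stats::rnorm(2 * d_out)),
         sage = list(W1 = matrix(stats::rnorm(d_out * d_in), d_out, d_in),
                     W2 = matrix(stats::rnorm(d_out * d_in), d_out, d_in)),
         gin = list(U1 = matrix(stats::rnorm(d_out * d_in), d_out, d_in),
                    b1 = stats::rnorm(d_out),
                    U2 = matrix(stats::rnorm(d_out * d_out), d_out, d_out),
                    b2 = stats::rnorm(d_out), eps = 0))
}

layer_oracle <- function(conv_type, X, arcs, params) {
  switch(conv_type,
         gcn = oracle_gcn(X, arcs, params$W),
         gat = oracle_gat(X, arcs, params$W, params$a),
         sage = oracle_sage(X, arcs, params$W1, params$W2),
         gin = oracle_gin(X, arcs, params$U1, params$b1, params$U2,
                          params$b2, params$eps))
}

# Largest implementation-vs-oracle deviation over `reps` random graphs.
layer_oracle_max_err <- function(conv_type, reps = 100, seed = 1) {
  set.seed(seed)
  worst <- 0
  for (r in seq_len(reps)) {
    n <- sample(2:8, 1)
    d_in <- sample(2:4, 1)
    d_out <- sample(2:4, 1)
    arcs <- random_arcs(n, p = 0.5)
    X <- matrix(stats::rnorm(n * d_in), n, d_in)
    params <- random_layer_params(conv_type, d_in, d_out)
    topo <- ns$build_topology(n, arcs)
    H <- ns$layer_forward(conv_type, X, topo, params, activation = FALSE)$H
    worst <- max(worst, max(abs(H - layer_oracle(conv_type, X, arcs, params))))
  }
  worst
}
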