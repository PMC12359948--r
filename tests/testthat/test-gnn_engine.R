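test_that("each message-passing layer matches its brute-force oracle", {
  for (ct in c("gcn", "gat", "sage", "gin")) {
    expect_lt(layer_oracle_max_err(ct, reps = 100, seed = 2024), 1e-6)
  }
})

test_that("GCN handles the hand-expanded special cases", {
  # isolated node: update collapses to the self term
  topo0 <- ns$build_topology(1L, matrix(integer(), 0, 2))
  h <- matrix(c(0.3, -0.7), 1, 2)
  fw <- ns$gcn_forward(h, topo0, list(W = diag(2)), activation = FALSE)
  expect_equal(fw$H, h)
  # two connected nodes, identity weights: both outputs are (0.5, 0.5)
  topo2 <- ns$build_topology(2L, rbind(c(1L, 2L), c(2L, 1L)))
  H <- rbind(c(1, 0), c(0, 1))
  fw2 <- ns$gcn_forward(H, topo2, list(W = diag(2)), activation = FALSE)
  expect_equal(fw2$H, rbind(c(0.5, 0.5), c(0.5, 0.5)), tolerance = 1e-12)
})

test_that("GAT attention is a proper softmax over the closed neighbourhood", {
  set.seed(4)
  for (r in 1:10) {
    n <- sample(3:8, 1)
    arcs <- random_arcs(n, 0.6)
    topo <- ns$build_topology(n, arcs)
    X <- matrix(stats::rnorm(n * 3), n, 3)
    params <- random_layer_params("gat", 3L, 4L)
    fw <- ns$gat_forward(X, topo, params, activation = FALSE)
    sums <- as.numeric(tapply(fw$alpha, fw$arcs_sl[, 2], sum))
    expect_equal(sums, rep(1, n), tolerance = 1e-12)
  }
  # zero attention vector gives uniform coefficients
  n <- 5L
  arcs <- random_arcs(n, 0.7)
  topo <- ns$build_topology(n, arcs)
  params <- list(W = matrix(stats::rnorm(12), 4, 3), a = numeric(8))
  fw <- ns$gat_forward(matrix(stats::rnorm(15), 5, 3), topo, params,
                       activation = FALSE)
  for (i in seq_len(n)) {
    al <- fw$alpha[fw$arcs_sl[, 2] == i]
    expect_equal(al, rep(1 / length(al), length(al)), tolerance = 1e-12)
  }
})

test_that("SAGE and GIN degenerate cases follow the operator definitions", {
  topo0 <- ns$build_topology(1L, matrix(integer(), 0, 2))
  h <- matrix(c(1, 2, 3), 1, 3)
  ps <- random_layer_params("sage", 3L, 2L)
  expect_equal(ns$sage_forward(h, topo0, ps, activation = FALSE)$H,
               h %*% t(ps$W1))
  pg <- random_layer_params("gin", 3L, 2L)
  expect_equal(ns$gin_forward(h, topo0, pg, activation = FALSE)$H,
               oracle_gin(h, matrix(integer(), 0, 2), pg$U1, pg$b1, pg$U2,
                          pg$b2))
  # two identical fully connected nodes produce identical embeddings
  topo2 <- ns$build_topology(2L, rbind(c(1L, 2L), c(2L, 1L)))
  hh <- rbind(c(1, -1, 2), c(1, -1, 2))
  out <- ns$gin_forward(hh, topo2, pg)$H
  expect_equal(out[1, ], out[2, ])
  # single-neighbour mean equals the neighbour embedding
  hx <- rbind(c(2, 4, 6), c(0, 0, 0))
  mh <- ns$aggregate_arcs(hx, topo2$src, topo2$dst, topo2$mean_w, 2L)
  expect_equal(mh[2, ], hx[1, ])
})

test_that("all layers are node-permutation equivariant", {
  set.seed(12)
  for (ct in c("gcn", "gat", "sage", "gin")) {
    n <- 7L
    arcs <- random_arcs(n, 0.5)
    X <- matrix(stats::rnorm(n * 3), n, 3)
    params <- random_layer_params(ct, 3L, 4L)
    perm <- sample(n)
    arcs_p <- cbind(match(arcs[, 1], perm), match(arcs[, 2], perm))
    H1 <- ns$layer_forward(ct, X, ns$build_topology(n, arcs), params)$H
    H2 <- ns$layer_forward(ct, X[perm, ], ns$build_topology(n, arcs_p),
                           params)$H
    expect_equal(H2, H1[perm, ], tolerance = 1e-6)
  }
})

test_that("model stack has the prescribed widths and pooled invariance", {
  cfg <- model_config("gcn", hidden_channels = 8L, seed = 3L)
  model <- xavier_init(cfg, d_node = 5L)
  expect_equal(dim(model$layers[[1]]$W), c(16L, 5L))
  expect_equal(dim(model$layers[[2]]$W), c(8L, 16L))
  expect_equal(dim(model$layers[[3]]$W), c(4L, 8L))
  expect_equal(dim(model$out$W), c(1L, 4L))
  expect_error(model_config("gcn", hidden_channels = 7L), "even")

  set.seed(8)
  graphs <- lapply(1:3, function(k) random_molecular_graph(4 + k, 5L))
  batch <- make_batch(graphs)
  out1 <- model_forward(model, batch)$logits
  expect_equal(dim(out1), c(3L, 1L))
  # evaluation mode is deterministic
  expect_identical(out1, model_forward(model, batch)$logits)
  # permuting graph order permutes logits
  batch2 <- make_batch(graphs[c(2, 3, 1)])
  out2 <- model_forward(model, batch2)$logits
  expect_equal(out2[, 1], out1[c(2, 3, 1), 1], tolerance = 1e-6)
  expect_error(make_batch(list()), "non-empty")
})

test_that("Xavier initialisation is seeded and follows the Glorot variance", {
  cfg <- model_config("gcn", hidden_channels = 8L)
  m1 <- xavier_init(cfg, d_node = 6L, seed = 11L)
  m2 <- xavier_init(cfg, d_node = 6L, seed = 11L)
  expect_identical(m1$layers, m2$layers)
  m3 <- xavier_init(cfg, d_node = 6L, seed = 12L)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))

  set.seed(1)
  W <- ns$glorot_uniform(512L, 512L)
  v_target <- 2 / (512 + 512)
  expect_lt(abs(stats::var(as.numeric(W)) - v_target) / v_target, 0.2)
})

test_that("logit losses are stable and consistent across modes", {
  l0 <- logit_loss(matrix(0), 1L, "binary")
  expect_equal(l0$loss, log(2), tolerance = 1e-12)
  expect_lt(logit_loss(matrix(30), 1L, "binary")$loss, 1e-12)
  lneg <- logit_loss(matrix(-100), 0L, "binary")
  expect_true(is.finite(lneg$loss))
  expect_lt(lneg$loss, 1e-12)
  # stable against the log-sum-exp reference at an extreme logit
  z <- -100
  ref <- log1p(exp(-abs(z))) + max(z, 0) - 0 * z
  expect_equal(logit_loss(matrix(z), 0L, "binary")$loss, ref)
  expect_error(logit_loss(matrix(0), 2L, "binary"), "labels")

  # two-logit model constrained to (0, z) equals the single-logit loss
  set.seed(3)
  for (k in 1:20) {
    z <- stats::rnorm(4, sd = 3)
    y <- sample(0:1, 4, replace = TRUE)
    b <- logit_loss(matrix(z, 4, 1), y, "binary")$loss
    t2 <- logit_loss(cbind(0, z), y, "two_class")$loss
    expect_equal(b, t2, tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences for every conv type", {
  set.seed(21)
  graphs <- list(random_molecular_graph(5L, 3L, label = 1L),
                 random_molecular_graph(4L, 3L, label = 0L))
  batch <- make_batch(graphs)
  eps <- 1e-6
  for (ct in c("gcn", "gat", "sage", "gin")) {
    cfg <- model_config(ct, hidden_channels = 4L, dropout = 0, seed = 9L)
    model <- xavier_init(cfg, d_node = 3L, d_edge = 2L, seed = 9L)
    # move off the zero-bias ReLU kink so both sides are differentiable
    for (l in 1:3) {
      for (nm in intersect(names(model$layers[[l]]), c("b1", "b2"))) {
        model$layers[[l]][[nm]] <-
          stats::rnorm(length(model$layers[[l]][[nm]]), sd = 0.3)
      }
    }
    model$out$b <- stats::rnorm(length(model$out$b), sd = 0.3)

    lossfn <- function(m) {
      fw <- model_forward(m, batch, training = TRUE)
      logit_loss(fw$logits, batch$labels, "binary")$loss
    }
    fw <- model_forward(model, batch, training = TRUE)
    ls <- logit_loss(fw$logits, batch$labels, "binary")
    gr <- ns$model_backward(model, batch, fw, ls$dlogits)

    worst <- 0
    probe <- function(get, set, ganal) {
      p <- get(model)
      for (t in seq_len(min(6L, length(p)))) {
        i <- sample(length(p), 1)
        gnum <- (lossfn(set(model, i, eps)) - lossfn(set(model, i, -eps))) /
          (2 * eps)
        denom <- max(abs(gnum) + abs(ganal[i]), 1e-6)
        worst <<- max(worst, abs(gnum - ganal[i]) / denom)
      }
    }
    for (l in 1:3) {
      for (nm in setdiff(names(model$layers[[l]]), "eps")) {
        probe(function(m) m$layers[[l]][[nm]],
              function(m, i, e) {
                m$layers[[l]][[nm]][i] <- m$layers[[l]][[nm]][i] + e
                m
              },
              gr$layers[[l]][[nm]])
      }
    }
    for (nm in c("W", "b")) {
      probe(function(m) m$out[[nm]],
            function(m, i, e) { m$out[[nm]][i] <- m$out[[nm]][i] + e; m },
            gr$out[[nm]])
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("checkpoints round-trip and reject incompatible schemas", {
  cfg <- model_config("sage", hidden_channels = 4L, seed = 2L)
  model <- xavier_init(cfg, d_node = 29L, d_edge = 6L)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path, schema = feature_schema("custom"))
  back <- load_checkpoint(path, schema = feature_schema("custom"))
  expect_equal(back$layers, model$layers, tolerance = 1e-15)
  expect_equal(back$out$W, model$out$W, tolerance = 1e-15)
  expect_error(load_checkpoint(path, schema = feature_schema("basic")),
               "incompatible")
})
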