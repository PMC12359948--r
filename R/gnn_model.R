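# Model construction, Xavier initialisation, batch assembly, the full
# forward/backward pass and the logit losses.
#
# The model is the three-layer stack used for every convolution type:
# widths 2h -> h -> h/2 with a rectifier after each convolution, dropout
# after layer 3, global mean pooling, and a final linear map to one logit
# (or two for the softmax cross-entropy variant).

#' Model configuration
#'
#' @param conv_type One of `"gcn"`, `"gat"`, `"sage"`, `"gin"`.
#' @param hidden_channels Even integer `>= 2`; the three convolution widths
#'   are `2 * hidden_channels`, `hidden_channels` and
#'   `hidden_channels / 2`.
#' @param dropout Dropout rate in \[0, 1) applied after the third
#'   convolution during training.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (graphs).
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @param max_epochs Epoch cap for one fit.
#' @param patience Early-stopping patience (epochs without validation-AUC
#'   improvement).
#' @param n_output_logits 1 for the sigmoid loss, 2 for the two-class
#'   softmax cross-entropy variant.
#' @param gin_eps Fixed (untrained) epsilon of the GIN sum aggregation.
#' @param gcn_edge_weight How GCN derives its scalar arc weight from the
#'   edge features: `"none"` (weight 1, the default) or `"bond_length"`
#'   (the reciprocal bond length, closer bonds weigh more).
#' @param gat_edge_attn If `TRUE`, GAT concatenates the edge features into
#'   the attention logit.
#' @return Object of class `model_config`.
#' @export
model_config <- function(conv_type = c("gcn", "gat", "sage", "gin"),
                         hidden_channels = 16L, dropout = 0.1,
                         learning_rate = 1e-3, batch_size = 32L, seed = 1L,
                         max_epochs = 500L, patience = 50L,
                         n_output_logits = 1L, gin_eps = 0,
                         gcn_edge_weight = c("none", "bond_length"),
                         gat_edge_attn = FALSE) {
  conv_type <- match.arg(conv_type)
  gcn_edge_weight <- match.arg(gcn_edge_weight)
  hidden_channels <- as.integer(hidden_channels)
  if (hidden_channels < 2L || hidden_channels %% 2L != 0L) {
    stop("hidden_channels must be an even integer >= 2")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (!n_output_logits %in% c(1L, 2L)) stop("n_output_logits must be 1 or 2")
  structure(list(conv_type = conv_type, hidden_channels = hidden_channels,
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_output_logits = as.integer(n_output_logits),
                 gin_eps = gin_eps, gcn_edge_weight = gcn_edge_weight,
                 gat_edge_attn = gat_edge_attn),
            class = "model_config")
}

glorot_uniform <- function(n_out, n_in) {
  b <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -b, b), n_out, n_in)
}

init_layer_params <- function(conv_type, d_in, d_out, d_edge = 0L,
                              gat_edge_attn = FALSE, gin_eps = 0) {
  switch(conv_type,
         gcn = list(W = glorot_uniform(d_out, d_in)),
         gat = {
           la <- 2L * d_out + if (gat_edge_attn) d_edge else 0L
           a <- as.numeric(glorot_uniform(1L, la))
           list(W = glorot_uniform(d_out, d_in), a = a)
         },
         sage = list(W1 = glorot_uniform(d_out, d_in),
                     W2 = glorot_uniform(d_out, d_in)),
         gin = list(U1 = glorot_uniform(d_out, d_in), b1 = numeric(d_out),
                    U2 = glorot_uniform(d_out, d_out), b2 = numeric(d_out),
                    eps = gin_eps))
}

#' Build and Xavier-initialise a model
#'
#' Every weight matrix is drawn from the Glorot uniform scheme
#' `U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out)))`; biases start
#' at zero; the GIN epsilon is a fixed constant. Reproducible for a fixed
#' seed.
#'
#' @param config A [model_config()].
#' @param d_node Node feature dimension of the graphs.
#' @param d_edge Edge feature dimension (used only by the GAT edge-attention
#'   option).
#' @param seed Overrides `config$seed` when given.
#' @return Object of class `gnn_model`: list with `config`, `d_node`,
#'   `d_edge`, `layers` (three per-layer parameter sets), `out`
#'   (final linear map).
#' @export
xavier_init <- function(config, d_node, d_edge = 0L, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  h <- config$hidden_channels
  dims <- c(d_node, 2L * h, h, h %/% 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- lapply(1:3, function(l) {
    init_layer_params(config$conv_type, dims[l], dims[l + 1L], d_edge,
                      config$gat_edge_attn, config$gin_eps)
  })
  out <- list(W = glorot_uniform(config$n_output_logits, dims[4L]),
              b = numeric(config$n_output_logits))
  structure(list(config = config, d_node = d_node, d_edge = d_edge,
                 seed = seed, layers = layers, out = out),
            class = "gnn_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Assemble a graph batch
#'
#' Stacks a set of molecular graphs into one block-diagonal batch: node
#' matrices are row-bound, arc indices offset, and a membership vector maps
#' every node to its graph.
#'
#' @param graphs List of `molecular_graph` objects.
#' @return Object of class `graph_batch`: list with `X`, `arcs`,
#'   `edge_matrix`, `graph_of`, `n_graphs`, `labels`.
#' @export
make_batch <- function(graphs) {
  if (!length(graphs)) stop("make_batch() requires a non-empty graph list")
  sizes <- vapply(graphs, function(g) as.integer(g$n_nodes), 0L)
  offsets <- cumsum(c(0L, sizes))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_matrix))
  arcs <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    a <- graphs[[k]]$arcs
    if (nrow(a)) a + offsets[k] else a
  }))
  edge_matrix <- do.call(rbind, lapply(graphs, function(g) g$edge_matrix))
  graph_of <- rep(seq_along(graphs), sizes)
  labels <- vapply(graphs, function(g) as.numeric(g$label[1]), 0)
  structure(list(X = X, arcs = arcs, edge_matrix = edge_matrix,
                 graph_of = graph_of, n_graphs = length(graphs),
                 labels = labels),
            class = "graph_batch")
}

batch_topology <- function(batch, config) {
  w <- NULL
  if (config$conv_type == "gcn" && config$gcn_edge_weight == "bond_length" &&
      nrow(batch$arcs) > 0) {
    len <- batch$edge_matrix[, ncol(batch$edge_matrix)]
    w <- ifelse(len > 0, 1 / len, 1)
  }
  build_topology(nrow(batch$X), batch$arcs, w)
}

# Global mean pooling: per-graph row means via grouped rowsum.
pool_mean <- function(H, graph_of, n_graphs) {
  counts <- tabulate(graph_of, nbins = n_graphs)
  rowsum_matrix(H, graph_of, n_graphs) / counts
}

#' Model forward pass
#'
#' Runs the three convolutions (rectifier after each), dropout (training
#' mode only), global mean pooling and the output linear map.
#'
#' @param model A `gnn_model`.
#' @param batch A `graph_batch`.
#' @param training If `TRUE`, applies inverted dropout after layer 3 and
#'   returns the caches needed for the backward pass. Evaluation mode is
#'   deterministic.
#' @param dropout_mask Optional precomputed dropout mask (used internally
#'   so a training step and its gradient check see the same mask).
#' @return List with `logits` (`n_graphs` x `n_output_logits`) and, when
#'   training, `cache`.
#' @export
model_forward <- function(model, batch, training = FALSE,
                          dropout_mask = NULL) {
  stopifnot(inherits(model, "gnn_model"), inherits(batch, "graph_batch"))
  if (batch$n_graphs < 1L) stop("empty batch")
  config <- model$config
  topo <- batch_topology(batch, config)
  edge_attr <- if (config$gat_edge_attn) batch$edge_matrix else NULL

  H <- batch$X
  caches <- vector("list", 3L)
  for (l in 1:3) {
    fw <- layer_forward(config$conv_type, H, topo, model$layers[[l]],
                        activation = TRUE, edge_attr = edge_attr)
    caches[[l]] <- fw$cache
    H <- fw$H
  }

  mask <- NULL
  H3 <- H
  if (training && config$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(length(H)) >= config$dropout,
                             nrow(H), ncol(H))
    }
    mask <- dropout_mask / (1 - config$dropout)
    H3 <- H * mask
  }

  P <- pool_mean(H3, batch$graph_of, batch$n_graphs)
  logits <- P %*% t(model$out$W) +
    matrix(model$out$b, batch$n_graphs, length(model$out$b), byrow = TRUE)

  if (!training) return(list(logits = logits))
  list(logits = logits,
       cache = list(topo = topo, caches = caches, mask = mask, P = P,
                    graph_of = batch$graph_of, H3 = H3))
}

# Backward pass from d(loss)/d(logits); returns gradients in the same
# nested shape as the model parameters.
model_backward <- function(model, batch, fw, dlogits) {
  config <- model$config
  cache <- fw$cache
  dW_out <- t(dlogits) %*% cache$P
  db_out <- colSums(dlogits)
  dP <- dlogits %*% model$out$W
  counts <- tabulate(cache$graph_of, nbins = nrow(dP))
  dH3 <- (dP / counts)[cache$graph_of, , drop = FALSE]
  if (!is.null(cache$mask)) dH3 <- dH3 * cache$mask

  grads_layers <- vector("list", 3L)
  dH <- dH3
  for (l in 3:1) {
    bw <- layer_backward(config$conv_type, dH, cache$caches[[l]], cache$topo,
                         model$layers[[l]])
    grads_layers[[l]] <- bw$grads
    dH <- bw$dH
  }
  list(layers = grads_layers, out = list(W = dW_out, b = db_out))
}

#' Classification loss on logits
#'
#' Binary mode: numerically stable sigmoid cross-entropy on a single logit
#' per graph. Two-class mode: softmax cross-entropy over two logits. The
#' mean over the batch is returned, along with the gradient with respect
#' to the logits.
#'
#' @param logits Matrix `n_graphs x n_output_logits`.
#' @param labels Integer labels in {0, 1}.
#' @param mode `"binary"` or `"two_class"`.
#' @return List with `loss` (scalar) and `dlogits` (same shape as
#'   `logits`).
#' @export
logit_loss <- function(logits, labels, mode = c("binary", "two_class")) {
  mode <- match.arg(mode)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be in {0, 1}")
  G <- nrow(logits)
  stopifnot(length(labels) == G)
  if (mode == "binary") {
    stopifnot(ncol(logits) == 1L)
    z <- logits[, 1]
    # softplus(z) - y z, evaluated stably
    loss <- mean(pmax(z, 0) - z * labels + log1p(exp(-abs(z))))
    p <- 1 / (1 + exp(-z))
    dlogits <- matrix((p - labels) / G, G, 1L)
  } else {
    stopifnot(ncol(logits) == 2L)
    mx <- pmax(logits[, 1], logits[, 2])
    lse <- mx + log(exp(logits[, 1] - mx) + exp(logits[, 2] - mx))
    picked <- ifelse(labels == 1, logits[, 2], logits[, 1])
    loss <- mean(lse - picked)
    pm <- exp(logits - cbind(lse, lse))
    onehot <- cbind(1 - labels, labels)
    dlogits <- (pm - onehot) / G
  }
  list(loss = loss, dlogits = dlogits)
}

# Positive-class probabilities in evaluation mode.
predict_prob <- function(model, batch) {
  logits <- model_forward(model, batch, training = FALSE)$logits
  if (model$config$n_output_logits == 1L) {
    1 / (1 + exp(-logits[, 1]))
  } else {
    mx <- pmax(logits[, 1], logits[, 2])
    ez <- exp(logits - cbind(mx, mx))
    ez[, 2] / rowSums(ez)
  }
}

#' Save a model checkpoint
#'
#' Writes config, parameter arrays, seed and a schema-compatibility stamp
#' (feature mode and dimensions) to a portable JSON container.
#'
#' @param model A `gnn_model`.
#' @param path Output path.
#' @param schema Optional [feature_schema()] recorded for compatibility
#'   checking at load time.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, schema = NULL) {
  payload <- list(
    container = "molgraphnn/checkpoint/v1",
    config = unclass(model$config),
    d_node = model$d_node, d_edge = model$d_edge, seed = model$seed,
    schema = if (is.null(schema)) NULL else
      list(mode = schema$mode, d_node = schema$d_node,
           d_edge = schema$d_edge),
    layers = model$layers,
    out = model$out
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Restores a model saved by [save_checkpoint()]. When `schema` is given,
#' loading fails if the checkpoint was trained under an incompatible
#' feature schema (different mode or dimensions).
#'
#' @param path Checkpoint path.
#' @param schema Optional [feature_schema()] the graphs to be scored use.
#' @return A `gnn_model`.
#' @export
load_checkpoint <- function(path, schema = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$container, "molgraphnn/checkpoint/v1")) {
    stop("not a molgraphnn checkpoint: ", path)
  }
  if (!is.null(schema) && !is.null(payload$schema)) {
    if (!identical(payload$schema$mode, schema$mode) ||
        payload$schema$d_node != schema$d_node ||
        payload$schema$d_edge != schema$d_edge) {
      stop("checkpoint is incompatible with the supplied feature schema")
    }
  }
  cfg <- payload$config
  config <- model_config(conv_type = cfg$conv_type,
                         hidden_channels = cfg$hidden_channels,
                         dropout = cfg$dropout,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, seed = cfg$seed,
                         max_epochs = cfg$max_epochs, patience = cfg$patience,
                         n_output_logits = cfg$n_output_logits,
                         gin_eps = cfg$gin_eps,
                         gcn_edge_weight = cfg$gcn_edge_weight,
                         gat_edge_attn = cfg$gat_edge_attn)
  fix <- function(p) {
    lapply(p, function(v) {
      if (is.list(v)) do.call(rbind, v) else v
    })
  }
  layers <- lapply(payload$layers, fix)
  out <- fix(payload$out)
  structure(list(config = config, d_node = payload$d_node,
                 d_edge = payload$d_edge, seed = payload$seed,
                 layers = layers, out = out),
            class = "gnn_model")
}
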