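# Minibatch Adam training with validation-AUC early stopping.

# Adam state mirrors the nested parameter structure.
adam_init <- function(params) {
  walk <- function(p) lapply(p, function(v) {
    if (is.list(v)) walk(v) else array(0, dim = dim(v) %||% length(v))
  })
  list(m = walk(params), v = walk(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next  # untrained constants (gin eps)
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  # the trainable parts of a model are $layers and $out
  r_layers <- upd(params$layers, grads$layers, state$m$layers, state$v$layers)
  r_out <- upd(params$out, grads$out, state$m$out, state$v$out)
  params$layers <- r_layers$p
  params$out <- r_out$p
  state$m$layers <- r_layers$m
  state$v$layers <- r_layers$v
  state$m$out <- r_out$m
  state$v$out <- r_out$v
  list(params = params, state = state)
}

#' Early-stopping epoch loop
#'
#' Drives an arbitrary per-epoch step function and halts when the monitored
#' score has not strictly improved for `patience` consecutive epochs, or at
#' `max_epochs`. The best epoch and score are reported so the caller can
#' restore the best-scoring state.
#'
#' @param step Function of the epoch index returning the validation score
#'   for that epoch (higher is better).
#' @param patience Epochs without improvement before halting.
#' @param max_epochs Hard epoch cap.
#' @return List with `epochs_run`, `best_epoch`, `best_score`, `history`.
#' @export
early_stopping_loop <- function(step, patience = 50L, max_epochs = 500L) {
  best_score <- -Inf
  best_epoch <- 0L
  history <- numeric(0)
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    s <- step(epoch)
    if (!is.finite(s)) stop("non-finite validation score at epoch ", epoch)
    history[epoch] <- s
    if (s > best_score) {
      best_score <- s
      best_epoch <- epoch
    } else if (epoch - best_epoch >= patience) {
      break
    }
  }
  list(epochs_run = epoch, best_epoch = best_epoch, best_score = best_score,
       history = history)
}

#' Train a model with early stopping
#'
#' Minibatch Adam training monitored by validation AUC: after every epoch
#' the model is scored on the validation graphs; training halts when the
#' AUC has not improved for `config$patience` epochs (or at
#' `config$max_epochs`), and the parameters are restored to the best-AUC
#' epoch.
#'
#' @param model A `gnn_model` (fresh from [xavier_init()] or warm-started).
#' @param train_graphs,val_graphs Lists of `molecular_graph` objects.
#' @param config Optional [model_config()] override; defaults to
#'   `model$config`.
#' @param rng_seed Seed for shuffling and dropout; defaults to
#'   `config$seed`.
#' @param audit Optional index-tracker environment (see
#'   [leakage_audit_new()]); when supplied, the graph ids touched here are
#'   recorded.
#' @return List with `model` (best-epoch parameters), `best_auc`,
#'   `epochs_run`, `best_epoch`, `history`.
#' @export
train_with_early_stopping <- function(model, train_graphs, val_graphs,
                                      config = NULL, rng_seed = NULL,
                                      audit = NULL) {
  config <- config %||% model$config
  if (!length(train_graphs) || !length(val_graphs)) {
    stop("training and validation sets must be non-empty")
  }
  if (!is.null(audit)) {
    leakage_audit_record(audit, "train",
                         vapply(train_graphs, function(g) g$graph_id, ""))
    leakage_audit_record(audit, "validation",
                         vapply(val_graphs, function(g) g$graph_id, ""))
  }
  loss_mode <- if (config$n_output_logits == 1L) "binary" else "two_class"
  val_batch <- make_batch(val_graphs)
  val_labels <- val_batch$labels
  n_train <- length(train_graphs)
  labels_train <- vapply(train_graphs, function(g) as.numeric(g$label[1]), 0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed %||% config$seed)

  state <- adam_init(list(layers = model$layers, out = model$out))
  best_model <- model

  step <- function(epoch) {
    perm <- sample.int(n_train)
    starts <- seq(1L, n_train, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n_train)]
      batch <- make_batch(train_graphs[idx])
      fw <- model_forward(model, batch, training = TRUE)
      ls <- logit_loss(fw$logits, labels_train[idx], loss_mode)
      if (!is.finite(ls$loss)) stop("non-finite training loss: diverged")
      grads <- model_backward(model, batch, fw, ls$dlogits)
      r <- adam_step(list(layers = model$layers, out = model$out), grads,
                     state, config$learning_rate)
      model$layers <<- r$params$layers
      model$out <<- r$params$out
      state <<- r$state
    }
    roc_auc(predict_prob(model, val_batch), val_labels)
  }

  # wrap step so that the best parameters are snapshotted when improved
  best_auc <- -Inf
  wrapped <- function(epoch) {
    s <- step(epoch)
    if (s > best_auc) {
      best_auc <<- s
      best_model <<- model
    }
    s
  }
  es <- early_stopping_loop(wrapped, patience = config$patience,
                            max_epochs = config$max_epochs)
  list(model = best_model, best_auc = es$best_score,
       epochs_run = es$epochs_run, best_epoch = es$best_epoch,
       history = es$history)
}
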