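# The training protocol: stratified nested cross-validation, grid search
# with combined-rank selection, seed reinitialisation, sequential warm
# starts with statistical stopping, and outer-fold evaluation with a
# leakage audit.

#' New leakage audit tracker
#'
#' An environment recording, per outer fold, every graph id touched by
#' training or selection. [evaluate_outer()] asserts that no outer-test id
#' was ever seen by its fold's training pipeline.
#'
#' @return An audit environment.
#' @export
leakage_audit_new <- function() {
  audit <- new.env(parent = emptyenv())
  audit$by_outer <- list()
  audit$outer <- NA_integer_
  audit
}

leakage_audit_set_outer <- function(audit, outer) {
  audit$outer <- outer
  if (length(audit$by_outer) < outer || is.null(audit$by_outer[[outer]])) {
    audit$by_outer[[outer]] <- character()
  }
  invisible(audit)
}

leakage_audit_record <- function(audit, stage, ids) {
  if (is.null(audit) || is.na(audit$outer)) return(invisible(NULL))
  o <- audit$outer
  audit$by_outer[[o]] <- union(audit$by_outer[[o]], ids)
  invisible(audit)
}

#' Stratified nested fold plan
#'
#' Splits indices into `outer_k` label-stratified outer folds; within each
#' outer iteration the remaining indices are split into `inner_k`
#' stratified inner folds. With the default 4 outer and 5 inner folds this
#' induces the 60/15/25 train/validation/test proportions.
#'
#' @param labels Binary label vector (0/1).
#' @param outer_k,inner_k Fold counts.
#' @param seed RNG seed for the stratified shuffles.
#' @return Object of class `fold_plan`: list with `outer_folds` (list of
#'   index vectors), `inner_folds` (list over outer folds of lists of index
#'   vectors), `outer_k`, `inner_k`, `seed`.
#' @export
make_fold_plan <- function(labels, outer_k = 4L, inner_k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n_min <- min(sum(labels == 0L), sum(labels == 1L))
  if (n_min < outer_k * inner_k) {
    stop("each class needs at least outer_k * inner_k = ",
         outer_k * inner_k, " members")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  deal <- function(idx, k) {
    idx <- sample(idx)
    split(idx, rep_len(seq_len(k), length(idx)))
  }
  strat_split <- function(indices, k) {
    folds <- replicate(k, integer(), simplify = FALSE)
    for (cls in c(0L, 1L)) {
      dealt <- deal(indices[labels[indices] == cls], k)
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], dealt[[f]])
    }
    lapply(folds, sort)
  }

  outer_folds <- strat_split(seq_along(labels), outer_k)
  inner_folds <- lapply(seq_len(outer_k), function(o) {
    rest <- sort(setdiff(seq_along(labels), outer_folds[[o]]))
    strat_split(rest, inner_k)
  })
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 outer_k = outer_k, inner_k = inner_k, seed = seed,
                 labels = labels),
            class = "fold_plan")
}

#' Default hyperparameter grid
#'
#' Candidate lists for batch size, hidden channels, dropout rate and
#' learning rate; the default enumerates 3 x 3 x 3 x 5 = 135 combinations.
#'
#' @return Named list of candidate vectors.
#' @export
default_hyperparameter_grid <- function() {
  list(batch_size = c(16L, 32L, 64L),
       hidden_channels = c(32L, 64L, 128L),
       dropout = c(0.1, 0.3, 0.5),
       learning_rate = c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2))
}

#' Enumerate a hyperparameter grid
#'
#' Cartesian product of the candidate lists in a deterministic order (the
#' first list varies fastest).
#'
#' @param grid Named list of non-empty candidate vectors.
#' @return Data frame with one row per combination, in enumeration order.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  if (any(!vapply(grid, length, 0L))) stop("empty candidate list in grid")
  expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Combined-rank selection
#'
#' Ranks trials descending by median validation AUC and, separately,
#' descending by minimum validation AUC; the winner minimises the sum of
#' the two ranks. Exact rank-sum ties go to the earliest enumeration index.
#'
#' @param trials List of trials, each a list with `id` and `aucs` (numeric
#'   vector of inner-fold validation AUCs).
#' @return List with `winner` (index into `trials`), `rank_sum` (vector),
#'   `median` and `min` per trial.
#' @export
combined_rank_select <- function(trials) {
  stopifnot(length(trials) >= 1L)
  med <- vapply(trials, function(t) stats::median(t$aucs), 0)
  mn <- vapply(trials, function(t) min(t$aucs), 0)
  rank_med <- rank(-med, ties.method = "average")
  rank_min <- rank(-mn, ties.method = "average")
  rs <- rank_med + rank_min
  winner <- which(rs == min(rs))[1]
  list(winner = winner, rank_sum = rs, median = med, min = mn)
}

derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  as.integer((sum(as.numeric(parts) * (7919 + seq_along(parts))) %%
                2147483629) + 1)
}

inner_fit <- function(dataset, plan, outer, fold, model, config, audit,
                      rng_seed) {
  inner <- plan$inner_folds[[outer]]
  val_idx <- inner[[fold]]
  train_idx <- sort(unlist(inner[-fold]))
  fit <- train_with_early_stopping(model, dataset$graphs[train_idx],
                                   dataset$graphs[val_idx], config,
                                   rng_seed = rng_seed, audit = audit)
  fit
}

#' Inner-loop grid search for one outer fold
#'
#' Trains every grid combination on each inner split (with early
#' stopping), collects the inner-fold validation AUCs, and returns the
#' combined-rank winner. A failed fit contributes AUC 0 and is logged in
#' the trial.
#'
#' @param dataset A `graph_dataset`.
#' @param plan A [make_fold_plan()].
#' @param outer_index Outer fold (1-based).
#' @param grid Hyperparameter grid (see [default_hyperparameter_grid()]).
#' @param base_config A [model_config()] supplying the fields the grid does
#'   not vary (conv type, patience, epochs, seed).
#' @param audit Optional leakage audit.
#' @return List with `best_config` (a `model_config`), `best_index`,
#'   `trials` (per-combination TrialScores), `selection`.
#' @export
inner_grid_search <- function(dataset, plan, outer_index, grid, base_config,
                              audit = NULL) {
  combos <- enumerate_grid(grid)
  if (!is.null(audit)) leakage_audit_set_outer(audit, outer_index)
  trials <- vector("list", nrow(combos))
  configs <- vector("list", nrow(combos))
  for (c_idx in seq_len(nrow(combos))) {
    cfg <- modify_config(base_config, combos[c_idx, , drop = FALSE])
    configs[[c_idx]] <- cfg
    aucs <- numeric(plan$inner_k)
    msgs <- character()
    for (f in seq_len(plan$inner_k)) {
      rs <- derive_seed(base_config$seed, outer_index, c_idx, f)
      fit <- tryCatch({
        model <- xavier_init(cfg, d_node = ncol(dataset$graphs[[1]]$node_matrix),
                             d_edge = dataset$schema$d_edge,
                             seed = derive_seed(cfg$seed, outer_index, c_idx))
        inner_fit(dataset, plan, outer_index, f, model, cfg, audit, rs)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        aucs[f] <- 0
        msgs <- c(msgs, conditionMessage(fit))
      } else {
        aucs[f] <- fit$best_auc
      }
    }
    trials[[c_idx]] <- list(id = c_idx, aucs = aucs, errors = msgs)
  }
  sel <- combined_rank_select(trials)
  list(best_config = configs[[sel$winner]], best_index = sel$winner,
       trials = trials, selection = sel)
}

modify_config <- function(base, row) {
  args <- unclass(base)
  for (nm in names(row)) args[[nm]] <- row[[nm]][1]
  do.call(model_config, args)
}

#' Seed-reinitialisation search for one outer fold
#'
#' With the hyperparameters fixed, trains a freshly Xavier-initialised
#' model per candidate seed on every inner split and selects the seed with
#' the best combined rank of median and minimum validation AUC.
#'
#' @param dataset A `graph_dataset`.
#' @param plan Fold plan.
#' @param outer_index Outer fold.
#' @param config The fold's winning [model_config()].
#' @param seeds Integer vector of candidate seeds (the full protocol uses
#'   20).
#' @param audit Optional leakage audit.
#' @return List with `best_seed`, `best_index`, `trials`, `selection`.
#' @export
seed_reinit_search <- function(dataset, plan, outer_index, config, seeds,
                               audit = NULL) {
  stopifnot(length(seeds) >= 1L)
  if (!is.null(audit)) leakage_audit_set_outer(audit, outer_index)
  trials <- vector("list", length(seeds))
  for (s_idx in seq_along(seeds)) {
    aucs <- numeric(plan$inner_k)
    for (f in seq_len(plan$inner_k)) {
      rs <- derive_seed(seeds[s_idx], outer_index, f, 1e6)
      fit <- tryCatch({
        model <- xavier_init(config,
                             d_node = ncol(dataset$graphs[[1]]$node_matrix),
                             d_edge = dataset$schema$d_edge,
                             seed = seeds[s_idx])
        inner_fit(dataset, plan, outer_index, f, model, config, audit, rs)
      }, error = function(e) e)
      aucs[f] <- if (inherits(fit, "error")) 0 else fit$best_auc
    }
    trials[[s_idx]] <- list(id = seeds[s_idx], aucs = aucs)
  }
  sel <- combined_rank_select(trials)
  list(best_seed = seeds[sel$winner], best_index = sel$winner,
       trials = trials, selection = sel)
}

#' One sequential warm-start run over the inner folds
#'
#' Trains the model on inner folds 1 to `inner_k` in order, each fold's
#' fit warm-started from the previous fold's best parameters (no
#' reinitialisation), with early stopping per fold. Emits the fold
#' validation AUCs and the final model state, which seeds the next run.
#'
#' @param model Current model state (winning seed's init for run 1, the
#'   previous run's final state afterwards).
#' @param dataset A `graph_dataset`.
#' @param plan Fold plan.
#' @param outer_index Outer fold.
#' @param config The fold's [model_config()].
#' @param run_index 1-based run number (only used to derive RNG streams).
#' @param audit Optional leakage audit.
#' @return List with `model` (updated state) and `aucs` (one per inner
#'   fold).
#' @export
warm_start_run <- function(model, dataset, plan, outer_index, config,
                           run_index = 1L, audit = NULL) {
  if (!is.null(audit)) leakage_audit_set_outer(audit, outer_index)
  aucs <- numeric(plan$inner_k)
  for (f in seq_len(plan$inner_k)) {
    rs <- derive_seed(config$seed, outer_index, run_index, f, 2e6)
    fit <- inner_fit(dataset, plan, outer_index, f, model, config, audit, rs)
    model <- fit$model
    aucs[f] <- fit$best_auc
  }
  list(model = model, aucs = aucs)
}

#' Warm-start stopping decision
#'
#' Before three completed runs, always continue. From run 3 onward, the
#' current run's pooled validation AUCs are compared against each of the
#' two previous runs with a one-sided Wilcoxon rank-sum test
#' (improvement direction); the warm starts halt iff both p-values exceed
#' the Sidak-corrected level for two comparisons.
#'
#' @param trace List of runs; each run is the numeric vector of pooled
#'   validation AUCs (20 in the full protocol: 5 inner folds x 4 outer
#'   folds).
#' @param alpha Family-wise significance level.
#' @return List with `decision` (`"continue"` or `"halt"`), `p_values`,
#'   `alpha_corrected`.
#' @export
stopping_decision <- function(trace, alpha = 0.05) {
  if (!is.list(trace) || !all(vapply(trace, is.numeric, TRUE))) {
    stop("trace must be a list of numeric AUC vectors")
  }
  a2 <- sidak_alpha(alpha, 2)
  r <- length(trace)
  if (r < 3L) {
    return(list(decision = "continue", p_values = numeric(0),
                alpha_corrected = a2))
  }
  cur <- trace[[r]]
  ps <- vapply(trace[c(r - 1L, r - 2L)], function(prev) {
    wilcoxon_rank_sum(cur, prev, "one_sided")$p_value
  }, 0)
  decision <- if (all(ps > a2)) "halt" else "continue"
  list(decision = decision, p_values = ps, alpha_corrected = a2)
}

#' Evaluate final models on the outer test folds
#'
#' Scores each outer fold's final warm-started model on that fold's
#' held-out test graphs, reports AUC/ACC/F1/MCC per fold and the mean and
#' standard deviation across folds, and verifies on the leakage audit that
#' no test graph id was touched during that fold's training or selection.
#'
#' @param models List of `gnn_model`, one per outer fold.
#' @param dataset A `graph_dataset`.
#' @param plan Fold plan.
#' @param audit Optional leakage audit; a recorded overlap raises an
#'   error.
#' @param threshold Classification threshold on the positive-class
#'   probability.
#' @return Object of class `outer_evaluation`: list with `per_fold` (data
#'   frame) and `aggregate` (mean/sd per metric).
#' @export
evaluate_outer <- function(models, dataset, plan, audit = NULL,
                           threshold = 0.5) {
  stopifnot(length(models) == plan$outer_k)
  rows <- vector("list", plan$outer_k)
  for (o in seq_len(plan$outer_k)) {
    test_idx <- plan$outer_folds[[o]]
    test_ids <- vapply(dataset$graphs[test_idx], function(g) g$graph_id, "")
    if (!is.null(audit)) {
      touched <- if (length(audit$by_outer) >= o) audit$by_outer[[o]] else
        character()
      overlap <- intersect(touched, test_ids)
      if (length(overlap)) {
        stop("leakage detected in outer fold ", o, ": ",
             paste(utils::head(overlap, 5), collapse = ", "))
      }
    }
    batch <- make_batch(dataset$graphs[test_idx])
    probs <- predict_prob(models[[o]], batch)
    m <- metric_report(probs, batch$labels, threshold)
    rows[[o]] <- data.frame(outer_fold = o, auc = m$auc, acc = m$acc,
                            f1 = m$f1, mcc = m$mcc)
  }
  per_fold <- do.call(rbind, rows)
  aggregate <- lapply(c(auc = "auc", acc = "acc", f1 = "f1", mcc = "mcc"),
                      function(col) {
                        list(mean = mean(per_fold[[col]]),
                             sd = stats::sd(per_fold[[col]]))
                      })
  structure(list(per_fold = per_fold, aggregate = aggregate),
            class = "outer_evaluation")
}

#' Run the full nested cross-validation protocol
#'
#' For each outer fold: grid search over the hyperparameter combinations
#' (combined-rank selection on the inner validation AUCs), seed
#' reinitialisation over the candidate seeds, then sequential warm-start
#' runs. After every run the pooled validation AUCs (all outer folds) are
#' tested against the two previous runs; the warm starts halt when no
#' significant improvement remains (never before three runs, never after
#' `max_runs`). The final per-fold models are evaluated on the held-out
#' outer test folds.
#'
#' @param dataset A `graph_dataset`.
#' @param base_config A [model_config()] supplying conv type, patience,
#'   epoch cap and base seed.
#' @param grid Hyperparameter grid.
#' @param seeds Candidate seeds for reinitialisation.
#' @param outer_k,inner_k Fold counts.
#' @param alpha Significance level of the stopping rule.
#' @param min_runs,max_runs Warm-start run bounds.
#' @param threshold Classification threshold.
#' @param verbose Print stage progress.
#' @return List with `plan`, `per_outer` (winning config/seed and trial
#'   records per fold), `warm_start_trace` (pooled AUCs and p-values per
#'   run), `runs_completed`, `evaluation` (an `outer_evaluation`),
#'   `audit`, `manifest`.
#' @export
run_nested_cv <- function(dataset, base_config,
                          grid = default_hyperparameter_grid(),
                          seeds = 1:20, outer_k = 4L, inner_k = 5L,
                          alpha = 0.05, min_runs = 3L, max_runs = 10L,
                          threshold = 0.5, verbose = FALSE) {
  labels <- dataset$labels
  plan <- make_fold_plan(labels, outer_k, inner_k, seed = base_config$seed)
  audit <- leakage_audit_new()
  say <- function(...) if (verbose) message(sprintf(...))

  per_outer <- vector("list", outer_k)
  models <- vector("list", outer_k)
  configs <- vector("list", outer_k)
  d_node <- ncol(dataset$graphs[[1]]$node_matrix)

  for (o in seq_len(outer_k)) {
    say("outer fold %d/%d: grid search over %d combinations", o, outer_k,
        nrow(enumerate_grid(grid)))
    gs <- inner_grid_search(dataset, plan, o, grid, base_config, audit)
    say("outer fold %d: seed search over %d seeds", o, length(seeds))
    ss <- seed_reinit_search(dataset, plan, o, gs$best_config, seeds, audit)
    configs[[o]] <- gs$best_config
    models[[o]] <- xavier_init(gs$best_config, d_node,
                               d_edge = dataset$schema$d_edge,
                               seed = ss$best_seed)
    per_outer[[o]] <- list(grid_search = gs, seed_search = ss,
                           best_seed = ss$best_seed)
  }

  trace <- list()
  run_records <- list()
  run <- 0L
  repeat {
    run <- run + 1L
    pooled <- numeric(0)
    per_fold_aucs <- vector("list", outer_k)
    for (o in seq_len(outer_k)) {
      ws <- warm_start_run(models[[o]], dataset, plan, o, configs[[o]],
                           run_index = run, audit = audit)
      models[[o]] <- ws$model
      per_fold_aucs[[o]] <- ws$aucs
      pooled <- c(pooled, ws$aucs)
    }
    trace[[run]] <- pooled
    dec <- stopping_decision(trace, alpha)
    run_records[[run]] <- list(run_index = run, pooled_aucs = pooled,
                               per_fold_aucs = per_fold_aucs,
                               p_values = dec$p_values,
                               decision = dec$decision)
    say("warm-start run %d: mean pooled AUC %.3f, decision %s", run,
        mean(pooled), dec$decision)
    if (run >= max_runs) break
    if (run >= min_runs && dec$decision == "halt") break
  }

  evaluation <- evaluate_outer(models, dataset, plan, audit, threshold)
  manifest <- list(conv_type = base_config$conv_type,
                   grid = grid, seeds = seeds, outer_k = outer_k,
                   inner_k = inner_k, alpha = alpha,
                   patience = base_config$patience,
                   max_epochs = base_config$max_epochs,
                   base_seed = base_config$seed,
                   runs_completed = run,
                   schema_mode = dataset$schema$mode)
  list(plan = plan, per_outer = per_outer, warm_start_trace = run_records,
       runs_completed = run, models = models, evaluation = evaluation,
       audit = audit, manifest = manifest)
}
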