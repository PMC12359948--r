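test_that("fold plans partition indices with stratified class counts", {
  labels <- c(rep(1L, 8), rep(0L, 4))
  plan <- make_fold_plan(labels, outer_k = 4L, inner_k = 1L, seed = 3L)
  for (f in plan$outer_folds) {
    expect_equal(sum(labels[f] == 1L), 2L)
    expect_equal(sum(labels[f] == 0L), 1L)
  }
  expect_setequal(unlist(plan$outer_folds), seq_along(labels))
  expect_equal(sum(lengths(plan$outer_folds)), length(labels))

  set.seed(41)
  for (rep in 1:100) {
    n <- sample(40:120, 1)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
    if (min(table(factor(labels, 0:1))) < 8) next
    plan <- make_fold_plan(labels, outer_k = 2L, inner_k = 4L, seed = rep)
    # outer folds partition everything
    expect_setequal(unlist(plan$outer_folds), seq_len(n))
    for (o in 1:2) {
      inner <- plan$inner_folds[[o]]
      rest <- setdiff(seq_len(n), plan$outer_folds[[o]])
      expect_setequal(unlist(inner), rest)
      for (cls in 0:1) {
        outer_counts <- vapply(plan$outer_folds,
                               function(f) sum(labels[f] == cls), 0L)
        expect_lte(max(outer_counts) - min(outer_counts), 1L)
        inner_counts <- vapply(inner, function(f) sum(labels[f] == cls), 0L)
        expect_lte(max(inner_counts) - min(inner_counts), 1L)
      }
    }
  }
  expect_error(make_fold_plan(c(rep(0L, 30), rep(1L, 3)), 4L, 5L),
               "at least")
})

test_that("grid enumeration is a deterministic cartesian product", {
  expect_equal(nrow(enumerate_grid(default_hyperparameter_grid())), 135L)
  expect_equal(nrow(enumerate_grid(list(a = 1))), 1L)
  expect_equal(nrow(enumerate_grid(list(a = 1:2, b = 1:3))), 6L)
  g1 <- enumerate_grid(list(a = 1:2, b = c(0.1, 0.2)))
  g2 <- enumerate_grid(list(a = 1:2, b = c(0.1, 0.2)))
  expect_identical(g1, g2)
  expect_error(enumerate_grid(list(a = integer())), "empty")
})

test_that("combined-rank selection follows the median/min rank sum", {
  trials <- list(list(id = "A", aucs = c(0.70, 0.70, 0.60)),
                 list(id = "B", aucs = c(0.72, 0.72, 0.55)),
                 list(id = "C", aucs = c(0.71, 0.71, 0.61)))
  sel <- combined_rank_select(trials)
  expect_equal(sel$winner, 3L)
  expect_equal(unname(sel$rank_sum), c(5, 4, 3))
  # single trial wins trivially; exact ties go to the earliest index
  expect_equal(combined_rank_select(trials[2])$winner, 1L)
  tie <- list(list(id = 1, aucs = c(0.6, 0.7, 0.8)),
              list(id = 2, aucs = c(0.6, 0.7, 0.8)))
  expect_equal(combined_rank_select(tie)$winner, 1L)
})

test_that("early stopping halts at exactly the patience on a flat score", {
  calls <- 0L
  es <- early_stopping_loop(function(e) { calls <<- calls + 1L; 0.5 },
                            patience = 50L, max_epochs = 500L)
  expect_equal(es$epochs_run, 51L)   # 50 flat epochs after the first
  expect_equal(calls, 51L)
  expect_equal(es$best_epoch, 1L)

  improving <- early_stopping_loop(function(e) e / 100, patience = 50L,
                                   max_epochs = 120L)
  expect_equal(improving$epochs_run, 120L)
  expect_equal(improving$best_epoch, 120L)

  noisy <- early_stopping_loop(function(e) sin(e), patience = 5L,
                               max_epochs = 100L)
  expect_equal(noisy$best_score, max(noisy$history))
})

test_that("training restores the best-AUC epoch and is reproducible", {
  ds <- small_graph_dataset("custom")
  cfg <- fast_config("gcn")
  idx <- seq_along(ds$graphs)
  val <- idx[idx %% 4 == 0]
  tr <- setdiff(idx, val)
  model <- xavier_init(cfg, ds$schema$d_node, ds$schema$d_edge, seed = 5L)
  fit1 <- train_with_early_stopping(model, ds$graphs[tr], ds$graphs[val], cfg,
                                    rng_seed = 123L)
  expect_equal(fit1$best_auc, max(fit1$history))
  # the returned parameters reproduce the reported best validation AUC
  val_probs <- ns$predict_prob(fit1$model, make_batch(ds$graphs[val]))
  expect_equal(roc_auc(val_probs, ds$labels[val]), fit1$best_auc,
               tolerance = 1e-12)
  fit2 <- train_with_early_stopping(model, ds$graphs[tr], ds$graphs[val], cfg,
                                    rng_seed = 123L)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$model$layers, fit2$model$layers, tolerance = 1e-15)
})

test_that("stopping decision enforces the run-3 minimum and the dual-p rule", {
  a2 <- sidak_alpha(0.05, 2)
  run <- function(mu) stats::rnorm(20, mu, 0.01)
  set.seed(6)
  expect_equal(stopping_decision(list(run(0.7)))$decision, "continue")
  expect_equal(stopping_decision(list(run(0.7), run(0.7)))$decision,
               "continue")

  # flat traces halt (both p-values large) ...
  flat <- stopping_decision(list(run(0.7), run(0.7), run(0.7)))
  expect_true(all(flat$p_values > a2))
  expect_equal(flat$decision, "halt")
  # ... improving traces continue (both comparisons significant)
  up <- stopping_decision(list(run(0.60), run(0.65), run(0.90)))
  expect_true(all(up$p_values < a2))
  expect_equal(up$decision, "continue")
  # one significant comparison is enough to continue
  mixed <- stopping_decision(list(run(0.60), run(0.90), run(0.90)))
  expect_equal(mixed$decision, "continue")
  expect_error(stopping_decision(list("x")), "numeric")
})

test_that("the stopping rule halts within 3-5 runs on exchangeable traces", {
  set.seed(17)
  halted_early <- 0L
  n_sim <- 200L
  for (s in seq_len(n_sim)) {
    trace <- list()
    halt_at <- NA_integer_
    for (r in 1:5) {
      trace[[r]] <- stats::rnorm(20, 0.7, 0.05)
      if (r >= 3 && stopping_decision(trace)$decision == "halt") {
        halt_at <- r
        break
      }
    }
    if (!is.na(halt_at)) halted_early <- halted_early + 1L
  }
  expect_gte(halted_early / n_sim, 0.9)
})

test_that("a one-combination grid search returns it with full trial scores", {
  ds <- small_graph_dataset("custom")
  plan <- make_fold_plan(ds$labels, outer_k = 2L, inner_k = 3L, seed = 2L)
  grid <- list(batch_size = 16L, hidden_channels = 4L, dropout = 0,
               learning_rate = 3e-3)
  gs <- inner_grid_search(ds, plan, 1L, grid, fast_config("gcn"))
  expect_equal(gs$best_index, 1L)
  expect_length(gs$trials, 1L)
  expect_length(gs$trials[[1]]$aucs, 3L)
  expect_true(all(gs$trials[[1]]$aucs >= 0 & gs$trials[[1]]$aucs <= 1))
})

test_that("seed search is deterministic and returns a listed seed", {
  ds <- small_graph_dataset("custom")
  plan <- make_fold_plan(ds$labels, outer_k = 2L, inner_k = 3L, seed = 2L)
  cfg <- fast_config("gcn")
  ss1 <- seed_reinit_search(ds, plan, 1L, cfg, seeds = c(3L, 14L))
  ss2 <- seed_reinit_search(ds, plan, 1L, cfg, seeds = c(3L, 14L))
  expect_true(ss1$best_seed %in% c(3L, 14L))
  expect_identical(ss1$best_seed, ss2$best_seed)
  expect_identical(lapply(ss1$trials, `[[`, "aucs"),
                   lapply(ss2$trials, `[[`, "aucs"))
  one <- seed_reinit_search(ds, plan, 1L, cfg, seeds = 42L)
  expect_equal(one$best_seed, 42L)
})

test_that("warm-start runs carry parameters across folds and emit 5n AUCs", {
  ds <- small_graph_dataset("custom")
  plan <- make_fold_plan(ds$labels, outer_k = 2L, inner_k = 3L, seed = 2L)
  cfg <- model_config("gcn", hidden_channels = 8L, dropout = 0,
                      learning_rate = 3e-3, batch_size = 16L, seed = 5L,
                      max_epochs = 30L, patience = 10L)
  model <- xavier_init(cfg, ds$schema$d_node, ds$schema$d_edge, seed = 3L)
  ws <- warm_start_run(model, ds, plan, 1L, cfg, run_index = 1L)
  expect_length(ws$aucs, plan$inner_k)
  # the state moved: warm-started parameters differ from the init
  state <- function(m) list(m$layers, m$out)
  expect_false(identical(state(ws$model), state(model)))
  # a second run warm-starts from the first's state, not from the init
  ws2 <- warm_start_run(ws$model, ds, plan, 1L, cfg, run_index = 2L)
  expect_false(identical(state(ws2$model), state(ws$model)))
})

test_that("the full protocol is leakage-free and reproducible end to end", {
  ds <- small_graph_dataset("custom")
  cfg <- fast_config("gcn")
  grid <- list(batch_size = c(16L, 32L), hidden_channels = 4L, dropout = 0,
               learning_rate = 3e-3)
  res1 <- run_nested_cv(ds, cfg, grid = grid, seeds = c(5L, 6L),
                        outer_k = 2L, inner_k = 3L, max_runs = 3L)
  # leakage audit: outer-test ids never touched by the fold's pipeline
  for (o in 1:2) {
    test_ids <- vapply(ds$graphs[res1$plan$outer_folds[[o]]],
                       function(g) g$graph_id, "")
    expect_length(intersect(res1$audit$by_outer[[o]], test_ids), 0L)
  }
  expect_equal(nrow(res1$evaluation$per_fold), 2L)
  agg <- res1$evaluation$aggregate
  expect_equal(agg$auc$mean, mean(res1$evaluation$per_fold$auc),
               tolerance = 1e-12)
  expect_equal(agg$mcc$sd, stats::sd(res1$evaluation$per_fold$mcc),
               tolerance = 1e-12)
  expect_gte(res1$runs_completed, 3L)

  res2 <- run_nested_cv(ds, cfg, grid = grid, seeds = c(5L, 6L),
                        outer_k = 2L, inner_k = 3L, max_runs = 3L)
  expect_equal(res1$evaluation$per_fold, res2$evaluation$per_fold,
               tolerance = 1e-6)

  # a poisoned audit triggers the hard leakage error
  poisoned <- res1$audit
  test_id1 <- vapply(ds$graphs[res1$plan$outer_folds[[1]]],
                     function(g) g$graph_id, "")[1]
  poisoned$by_outer[[1]] <- c(poisoned$by_outer[[1]], test_id1)
  expect_error(evaluate_outer(res1$models, ds, res1$plan, poisoned),
               "leakage")
})
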