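# Orchestration: hyperparameter grid search, the artificial-benchmark
# experiment runner, and evaluation utilities.

#' Accuracy and confusion matrix
#'
#' @param predictions,truth equal-length integer class vectors.
#' @param n_classes number of classes (default: largest label seen).
#' @return list with `accuracy` (fraction of exact matches) and `confusion`
#'   (rows = truth, columns = predicted).
#' @export
evaluate <- function(predictions, truth,
                     n_classes = max(c(predictions, truth))) {
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  lev <- seq_len(n_classes)
  confusion <- table(truth = factor(truth, lev),
                     predicted = factor(predictions, lev))
  list(accuracy = mean(predictions == truth),
       confusion = unclass(confusion))
}

#' Exhaustive grid search over ensemble hyperparameters
#'
#' Fits the evidence ensemble for every combination of the supplied grids
#' and returns the configuration maximizing validation accuracy. Ties are
#' broken toward the smaller hidden size, then the smaller learning rate,
#' then the smaller theta.
#'
#' @param train_views,val_views lists of [feature_space_view()]s.
#' @param grids list with any of `hidden` (hidden units), `learning_rate`,
#'   and `theta`; missing entries fall back to the values in `base`.
#' @param base an [ensemble_config()] supplying everything not in the grid.
#' @return list with `config` (the chosen `ensemble_config`), `table` (a
#'   data frame of all grid points and their validation accuracies), and
#'   `val_accuracy`.
#' @export
tune <- function(train_views, val_views, grids, base = ensemble_config()) {
  hidden <- if (!is.null(grids$hidden)) as.integer(grids$hidden)
            else base$expert_mlp$hidden_units
  lrs <- if (!is.null(grids$learning_rate)) grids$learning_rate
         else base$expert_mlp$learning_rate
  thetas <- if (!is.null(grids$theta)) grids$theta else base$theta
  grid <- expand.grid(theta = sort(thetas), learning_rate = sort(lrs),
                      hidden = sort(hidden))
  # evaluation order guarantees the tie-break: first (smallest h, lr, theta)
  grid <- grid[order(grid$hidden, grid$learning_rate, grid$theta), ]
  acc <- numeric(nrow(grid))
  best <- NULL; best_acc <- -Inf
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    cfg$theta <- grid$theta[i]
    cfg$expert_mlp$hidden_units <- grid$hidden[i]
    cfg$expert_mlp$learning_rate <- grid$learning_rate[i]
    cfg$relabel_mlp$hidden_units <- grid$hidden[i]
    cfg$relabel_mlp$learning_rate <- grid$learning_rate[i]
    ens <- fit_evidence_ensemble(train_views, val_views, cfg)
    acc[i] <- mean(predict(ens, lapply(val_views, `[[`, "x")) ==
                     val_views[[1L]]$y)
    if (acc[i] > best_acc) {
      best <- cfg; best_acc <- acc[i]
    }
  }
  grid$val_accuracy <- acc
  list(config = best, table = grid, val_accuracy = best_acc)
}

experiment_methods <- c("proposed", "knn_relabel_variant", "average",
                        "product", "maximum", "minimum",
                        "decision_templates", "single_view_mlps")

#' Run the artificial-benchmark experiment
#'
#' For every triangle side in `d_values` and every seed: generate the three
#' complementary views, fit the requested methods, and evaluate them on the
#' test set. The evidential methods (`proposed`, `knn_relabel_variant`)
#' relabel per view and fuse through Dempster's rule; the fixed rules and
#' decision templates share one stack of per-view networks trained on the
#' original labels; `single_view_mlps` reports each view's own network
#' (rows `single_view1..3`).
#'
#' @param d_values triangle side lengths (default `c(1, 2, 3)`).
#' @param seeds integer vector of generator/training seeds.
#' @param methods subset of
#'   `c("proposed", "knn_relabel_variant", "average", "product", "maximum",
#'   "minimum", "decision_templates", "single_view_mlps")`.
#' @param cfg an [ensemble_config()] shared by all methods.
#' @param n_train,n_val,n_test set totals (defaults 150/300/500).
#' @param verbose print one line per run.
#' @return an object of class `experiment_report`: `results` (data frame of
#'   method, d, seed, accuracy), `confusion` (nested list of confusion
#'   matrices), `failures` (count), and the configuration.
#' @export
run_artificial_experiment <- function(d_values = c(1, 2, 3),
                                      seeds = 1:10,
                                      methods = experiment_methods,
                                      cfg = ensemble_config(),
                                      n_train = 150L, n_val = 300L,
                                      n_test = 500L, verbose = FALSE) {
  methods <- match.arg(methods, experiment_methods, several.ok = TRUE)
  rows <- list(); confusion <- list(); failures <- 0L
  add_row <- function(method, d, seed, pred, truth) {
    ev <- evaluate(pred, truth, n_classes = 3L)
    rows[[length(rows) + 1L]] <<- data.frame(method = method, d = d,
                                             seed = seed,
                                             accuracy = ev$accuracy)
    confusion[[paste(method, d, seed, sep = "/")]] <<- ev$confusion
  }
  for (d in d_values) for (seed in seeds) {
    run <- function() {
      td <- make_triangle_views(triangle_spec(d = d, n_train = n_train,
                                              n_val = n_val, n_test = n_test,
                                              seed = seed))
      tv <- triangle_fsv(td, "train")
      vv <- triangle_fsv(td, "val")
      xt <- lapply(td$views, `[[`, "test")
      yt <- td$labels$test
      seed_cfg <- cfg
      seed_cfg$relabel_mlp$seed <- cfg$relabel_mlp$seed + seed
      seed_cfg$expert_mlp$seed <- cfg$expert_mlp$seed + seed
      if ("proposed" %in% methods) {
        ens <- fit_evidence_ensemble(tv, vv, seed_cfg)
        add_row("proposed", d, seed, predict(ens, xt), yt)
      }
      if ("knn_relabel_variant" %in% methods) {
        kcfg <- seed_cfg; kcfg$relabel_method <- "knn"
        ens <- fit_evidence_ensemble(tv, vv, kcfg)
        add_row("knn_relabel_variant", d, seed, predict(ens, xt), yt)
      }
      fixed <- intersect(methods, c("average", "product", "maximum",
                                    "minimum", "decision_templates",
                                    "single_view_mlps"))
      if (length(fixed)) {
        pe <- fit_profile_ensemble(tv, vv, seed_cfg)
        for (rule in intersect(fixed, c("average", "product", "maximum",
                                        "minimum")))
          add_row(rule, d, seed, predict_fixed_rule(pe, xt, rule), yt)
        if ("decision_templates" %in% fixed) {
          dt <- decision_templates_fit(
            decision_profiles(pe, lapply(td$views, `[[`, "train")),
            td$labels$train)
          pred <- vapply(decision_profiles(pe, xt),
                         decision_templates_predict, integer(1), dt = dt)
          add_row("decision_templates", d, seed, pred, yt)
        }
        if ("single_view_mlps" %in% fixed)
          for (v in 1:3) {
            post <- expert_mass_matrix(pe$experts[[v]], xt[[v]])
            add_row(paste0("single_view", v), d, seed,
                    max.col(post %*% pe$experts[[v]]$pignistic_map, "first"),
                    yt)
          }
      }
    }
    ok <- tryCatch({ run(); TRUE },
                   error = function(e) {
                     warning("run d=", d, " seed=", seed, " failed: ",
                             conditionMessage(e))
                     FALSE
                   })
    if (!ok) failures <- failures + 1L
    if (verbose) message("d=", d, " seed=", seed,
                         if (ok) " done" else " FAILED")
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, confusion = confusion,
                 failures = failures, cfg = cfg,
                 d_values = d_values, seeds = seeds),
            class = "experiment_report")
}

#' Per-method mean accuracies of an experiment report
#'
#' @param report an `experiment_report`.
#' @return data frame of method, d, mean and sd accuracy, and run count.
#' @export
summarize_experiment <- function(report) {
  r <- report$results
  agg <- aggregate(accuracy ~ method + d, data = r,
                   FUN = function(a) c(mean = mean(a), sd = stats::sd(a),
                                       n = length(a)))
  out <- data.frame(method = agg$method, d = agg$d,
                    mean_accuracy = agg$accuracy[, "mean"],
                    sd_accuracy = agg$accuracy[, "sd"],
                    n = agg$accuracy[, "n"])
  out[order(out$d, -out$mean_accuracy), ]
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d runs (%d failed)\n",
              nrow(x$results), x$failures))
  print(summarize_experiment(x), row.names = FALSE)
  invisible(x)
}
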