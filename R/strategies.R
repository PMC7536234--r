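#' Run one classification strategy on a per-patient split feature table
#'
#' Prunes correlated features on the training images, fits the requested
#' strategy, finds the Youden-optimal cutoff on training scores, and
#' evaluates accuracy, sensitivity, specificity, PPV, NPV and Cohen's kappa
#' on both sides of the split. Test metrics are computed only on held-out
#' patients' images, with the cutoff frozen from training.
#'
#' Strategies: `"A"` logistic regression and `"B"` RBF-SVM, both with the
#' kappa/Youden forward selection wrapper; `"C"` gradient-boosted trees with
#' grid search over patient-grouped 5-fold CV error; `"D"` genetic pipeline
#' search over the same CV criterion.
#'
#' @param train,test feature tables (rows = images) from [extract_cohort()],
#'   split per patient.
#' @param strategy one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param r_threshold Pearson pruning cutoff (default 0.9).
#' @param seed integer seed for the stochastic strategies.
#' @param xgb_grid hyperparameter grid for strategy C.
#' @param ga a [ga_config()] for strategy D.
#' @return list of class `strategy_result`: `strategy`, `selected`,
#'   `cutoff`, `train_metrics`, `test_metrics`, plus strategy extras
#'   (`trace`, `config`, `genome`, `gain`, `history`).
#' @export
run_strategy <- function(train, test, strategy = c("A", "B", "C", "D"),
                         r_threshold = 0.9, seed = 1L,
                         xgb_grid = default_xgb_grid(), ga = ga_config()) {
  strategy <- match.arg(strategy)
  stopifnot(!any(train$patient_id %in% test$patient_id))
  feats <- .feature_cols(train)
  retained <- correlation_prune(train[, feats, drop = FALSE], r_threshold)
  Xtr <- as.matrix(train[, retained, drop = FALSE])
  Xte <- as.matrix(test[, retained, drop = FALSE])
  ytr <- train$label; yte <- test$label
  extras <- list()
  if (strategy %in% c("A", "B")) {
    family <- if (strategy == "A") "logistic" else "svm_rbf"
    fs <- forward_select(family, Xtr, ytr)
    scorer <- function(Xn) fs$scorer(Xn[, fs$selected, drop = FALSE])
    cutoff <- fs$cutoff
    selected <- fs$selected
    extras$trace <- fs$trace
  } else if (strategy == "C") {
    fit <- fit_strategy_C(Xtr, ytr, groups = train$patient_id,
                          grid = xgb_grid, seed = seed)
    scorer <- fit$scorer
    cutoff <- fit$cutoff
    selected <- retained
    extras$config <- fit$config
    extras$gain <- feature_gain(fit$model, retained)
    extras$model <- fit$model
  } else {
    fit <- fit_strategy_D(Xtr, ytr, groups = train$patient_id,
                          config = ga, seed = seed)
    scorer <- fit$scorer
    cutoff <- fit$cutoff
    selected <- retained
    extras$genome <- fit$genome
    extras$history <- fit$history
  }
  eval_at <- function(X, y) {
    sc <- scorer(X)
    pred <- ifelse(sc >= cutoff, "carrier", "wild_type")
    .cm_metrics(confusion_matrix(pred, y))
  }
  structure(c(list(strategy = strategy, selected = selected, cutoff = cutoff,
                   train_metrics = eval_at(Xtr, ytr),
                   test_metrics = eval_at(Xte, yte)),
              extras),
            class = "strategy_result")
}
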