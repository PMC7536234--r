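# Classification strategies. The positive class is "carrier" throughout and
# the classification rule is score >= cutoff => carrier.

.META_COLS <- c("image_id", "patient_id", "machine", "label")

.feature_cols <- function(table) setdiff(names(table), .META_COLS)

#' Patient-level stratified train/test split
#'
#' Partitions patients (never images) into train and test sets so that no
#' patient contributes to both sides; stratified by patient label, with the
#' train fraction applied to each stratum's patient count and rounded to
#' nearest.
#'
#' @param table feature table with `patient_id` and `label` columns.
#' @param train_fraction fraction of patients in the training set
#'   (default 0.75).
#' @param seed optional integer seed for the patient shuffle.
#' @param stratify stratify by patient label (default TRUE).
#' @return list with `train` and `test` character vectors of patient ids.
#' @export
split_patients <- function(table, train_fraction = 0.75, seed = NULL,
                           stratify = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  pat <- unique(table[, c("patient_id", "label")])
  if (any(tabulate(factor(pat$label)) < 2))
    stop("split error: every class needs at least 2 patients")
  if (!is.null(seed)) set.seed(seed)
  strata <- if (stratify) split(pat$patient_id, pat$label)
            else list(all = pat$patient_id)
  train <- unlist(lapply(strata, function(ids) {
    n_tr <- min(length(ids) - 1L, max(1L, round(train_fraction * length(ids))))
    .resample(ids, n_tr)
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(pat$patient_id, train)))
}

# stratified patient-grouped fold assignment; returns named fold index per
# patient id
.patient_folds <- function(patient_ids, labels, k = 5L) {
  pat <- unique(data.frame(patient_id = patient_ids, label = labels,
                           stringsAsFactors = FALSE))
  fold <- integer(nrow(pat))
  names(fold) <- pat$patient_id
  for (cl in unique(pat$label)) {
    ids <- .resample(pat$patient_id[pat$label == cl],
                     sum(pat$label == cl)) # shuffle
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

#' Confusion matrix counts at a fixed rule
#'
#' @param predicted,truth vectors of class labels.
#' @param positive the positive class (default `"carrier"`).
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, truth, positive = "carrier") {
  list(tp = sum(predicted == positive & truth == positive),
       fp = sum(predicted == positive & truth != positive),
       tn = sum(predicted != positive & truth != positive),
       fn = sum(predicted != positive & truth == positive))
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with
#' `po = (tp + tn) / n` and
#' `pe = ((tp + fn)(tp + fp) + (fp + tn)(fn + tn)) / n^2`; when `pe = 1`
#' (a degenerate table) kappa is defined as 0.
#'
#' @param cm list with `tp`, `fp`, `tn`, `fn` (see [confusion_matrix()]).
#' @return list with `po`, `pe`, `kappa`.
#' @export
cohen_kappa <- function(cm) {
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  stopifnot(n > 0)
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
         (cm$fp + cm$tn) * (cm$fn + cm$tn)) / n^2
  kappa <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
  list(po = po, pe = pe, kappa = kappa)
}

# accuracy / Se / Sp / PPV / NPV / kappa of a confusion matrix
.cm_metrics <- function(cm) {
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  c(accuracy = (cm$tp + cm$tn) / n,
    sensitivity = .sdiv(cm$tp, cm$tp + cm$fn),
    specificity = .sdiv(cm$tn, cm$tn + cm$fp),
    ppv = .sdiv(cm$tp, cm$tp + cm$fp),
    npv = .sdiv(cm$tn, cm$tn + cm$fn),
    kappa = cohen_kappa(cm)$kappa)
}

#' ROC curve and Youden-optimal cutoff
#'
#' Candidate thresholds are the sorted unique scores plus `+Inf`; an
#' observation is called positive when its score is at or above the
#' threshold. The optimal cutoff maximizes the Youden index
#' `J = Se + Sp - 1`; ties are broken by the lowest threshold.
#'
#' @param scores numeric scores (higher means more carrier-like).
#' @param labels class labels.
#' @param positive positive class (default `"carrier"`).
#' @return list with `curve` (data frame: threshold, sensitivity,
#'   specificity, J), `cutoff` and `J`.
#' @export
roc_youden <- function(scores, labels, positive = "carrier") {
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos))
    stop("ROC error: both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  se <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  sp <- vapply(thr, function(t) mean(scores[!is_pos] < t), numeric(1))
  j <- se + sp - 1
  best <- which.max(j) # which.max returns the first (lowest threshold) tie
  list(curve = data.frame(threshold = thr, sensitivity = se,
                          specificity = sp, J = j),
       cutoff = thr[best], J = j[best])
}

# ---- base learners -------------------------------------------------------

# standardization statistics from training data
.std_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  list(mu = mu, sd = sd_)
}
.std_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

# fit logistic or RBF-SVM scorer on a feature matrix; returns a closure
# mapping new feature matrices to scores oriented towards "carrier"
.fit_scorer <- function(family, X, y) {
  y01 <- as.integer(y == "carrier")
  if (family == "logistic") {
    df <- as.data.frame(X)
    fit <- suppressWarnings(
      stats::glm(y01 ~ ., data = cbind(y01 = y01, df),
                 family = stats::binomial()))
    function(Xn) {
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(Xn), type = "response")))
    }
  } else if (family == "svm_rbf") {
    st <- .std_fit(X)
    fit <- e1071::svm(.std_apply(X, st), factor(y, c("wild_type", "carrier")),
                      kernel = "radial", cost = 1, scale = FALSE)
    function(Xn) {
      dv <- attr(stats::predict(fit, .std_apply(Xn, st),
                                decision.values = TRUE), "decision.values")
      # orient decision values so higher means carrier
      if (grepl("^carrier", colnames(dv)[1])) as.numeric(dv) else -as.numeric(dv)
    }
  } else stop("unknown model family: ", family)
}

#' Kappa/Youden forward feature selection for logistic or RBF-SVM models
#'
#' The wrapper the pipeline uses for strategies A and B. Starting from one
#' feature: every candidate model extending the held set by one feature is
#' fitted on the training images; each is scored by the Cohen's kappa of
#' its training confusion matrix at its own Youden-optimal ROC cutoff; the
#' best candidate is kept (ties go to the earlier feature in table order);
#' the iteration stops when no candidate strictly increases kappa.
#'
#' @param family `"logistic"` or `"svm_rbf"`.
#' @param X training feature matrix/data frame (already pruned).
#' @param y training labels.
#' @return list: `selected` (feature names in selection order), `trace`
#'   (data frame feature/kappa, strictly increasing), `scorer` (the final
#'   fitted scoring closure), `cutoff`, `kappa`.
#' @export
forward_select <- function(family, X, y) {
  X <- as.matrix(X)
  pool <- colnames(X)
  if (!length(pool)) stop("selection error: empty feature pool")
  held <- character(0)
  best_kappa <- -Inf
  trace <- list()
  best_scorer <- NULL; best_cutoff <- NA_real_
  repeat {
    step_best <- NULL
    for (cand in setdiff(pool, held)) {
      feats <- c(held, cand)
      scorer <- .fit_scorer(family, X[, feats, drop = FALSE], y)
      sc <- scorer(X[, feats, drop = FALSE])
      ry <- roc_youden(sc, y)
      pred <- ifelse(sc >= ry$cutoff, "carrier", "wild_type")
      kap <- cohen_kappa(confusion_matrix(pred, y))$kappa
      if (is.null(step_best) || kap > step_best$kappa) {
        step_best <- list(feature = cand, kappa = kap,
                          scorer = scorer, cutoff = ry$cutoff)
      }
    }
    if (is.null(step_best) || step_best$kappa <= best_kappa) break
    held <- c(held, step_best$feature)
    best_kappa <- step_best$kappa
    best_scorer <- step_best$scorer
    best_cutoff <- step_best$cutoff
    trace[[length(trace) + 1]] <-
      data.frame(feature = step_best$feature, kappa = step_best$kappa,
                 stringsAsFactors = FALSE)
    if (length(held) == length(pool)) break
  }
  list(selected = held,
       trace = do.call(rbind, trace),
       scorer = best_scorer, cutoff = best_cutoff, kappa = best_kappa)
}

# ---- boosted trees (strategy C) ------------------------------------------

#' Default hyperparameter grid for the boosted-tree strategy
#'
#' @return data frame over depth, learning rate, tree count and subsample.
#' @export
default_xgb_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L),
              eta = c(0.05, 0.1, 0.3),
              nrounds = c(50L, 100L, 200L),
              subsample = c(0.7, 1.0))
}

.fit_xgb <- function(X, y01, cfg) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = cfg$max_depth,
                  eta = cfg$eta, subsample = cfg$subsample,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(as.matrix(X), label = y01),
    nrounds = cfg$nrounds, verbose = 0)
}

#' Boosted-tree strategy: grid search with patient-grouped cross-validation
#'
#' Grid-searches gradient-boosted tree hyperparameters by 5-fold
#' cross-validated misclassification error with folds grouped (and
#' stratified) by patient, selects the error-minimizing configuration
#' (first in grid order on ties), and refits it on the full training set.
#'
#' @param X training feature matrix (already pruned).
#' @param y training labels.
#' @param groups patient id per training row.
#' @param grid hyperparameter data frame (default [default_xgb_grid()]).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (fold assignment and subsampling).
#' @return list: `model` (xgb.Booster), `config`, `cv_error`, `scorer`,
#'   `cutoff`, `cv_table`.
#' @export
fit_strategy_C <- function(X, y, groups, grid = default_xgb_grid(),
                           folds = 5L, seed = 1L) {
  if (!nrow(grid)) stop("config error: empty hyperparameter grid")
  X <- as.matrix(X)
  y01 <- as.integer(y == "carrier")
  set.seed(seed)
  fold_of <- .patient_folds(groups, y, k = folds)
  row_fold <- fold_of[groups]
  cv_err <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- row_fold != f
      if (!any(!tr) || length(unique(y01[tr])) < 2) return(NA_real_)
      fit <- .fit_xgb(X[tr, , drop = FALSE], y01[tr], grid[i, ])
      p <- stats::predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
      mean((p >= 0.5) != y01[!tr])
    }, numeric(1))
    cv_err[i] <- mean(errs, na.rm = TRUE)
  }
  best <- which.min(cv_err)
  model <- .fit_xgb(X, y01, grid[best, ])
  scorer <- function(Xn)
    stats::predict(model, xgboost::xgb.DMatrix(as.matrix(Xn)))
  sc <- scorer(X)
  ry <- roc_youden(sc, y)
  list(model = model, config = grid[best, ], cv_error = cv_err[best],
       scorer = scorer, cutoff = ry$cutoff,
       cv_table = cbind(grid, cv_error = cv_err))
}

#' Per-feature total gain of a fitted boosted-tree model
#'
#' @param model an `xgb.Booster` as returned by [fit_strategy_C()].
#' @param feature_names feature names used at fit time.
#' @return data frame `feature`, `gain` (descending; unused features 0).
#' @export
feature_gain <- function(model, feature_names) {
  imp <- tryCatch(xgboost::xgb.importance(model = model),
                  error = function(e) NULL)
  gain <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp))
    gain[imp$Feature] <- imp$Gain
  out <- data.frame(feature = names(gain), gain = as.numeric(gain),
                    stringsAsFactors = FALSE)
  out[order(-out$gain), , drop = FALSE]
}
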