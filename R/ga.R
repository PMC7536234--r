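# Genetic pipeline search (strategy D): a small genetic algorithm over
# (preprocessor, model family, hyperparameters) genomes, minimizing the
# patient-grouped 5-fold cross-validated misclassification error.

#' Genetic-search configuration
#'
#' @param population genome count per generation (>= 2, default 24).
#' @param generations number of generations (default 8).
#' @param tournament tournament size for parent selection (default 3).
#' @param p_crossover per-mating uniform-crossover probability (default 0.8).
#' @param p_mutation per-gene mutation probability (default 0.2).
#' @param folds CV folds (default 5).
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population = 24L, generations = 8L, tournament = 3L,
                      p_crossover = 0.8, p_mutation = 0.2, folds = 5L) {
  if (population < 2) stop("config error: population must be at least 2")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 folds = as.integer(folds)),
            class = "ga_config")
}

.GENE_SPACE <- list(
  preproc = c("none", "varfilter"),
  model = c("logistic", "svm_rbf", "boosted_trees", "random_forest"),
  cost = c(0.1, 1, 10),            # svm
  depth = c(2L, 3L, 4L),           # boosted trees
  eta = c(0.05, 0.1, 0.3),
  nrounds = c(50L, 100L, 200L),
  ntree = c(100L, 300L),           # random forest
  mtry_frac = c(0.2, 0.5, 0.8)
)

.random_genome <- function() {
  lapply(.GENE_SPACE, function(v) .resample(v, 1))
}

.mutate_genome <- function(g, p) {
  for (nm in names(g)) if (stats::runif(1) < p) g[[nm]] <- .resample(.GENE_SPACE[[nm]], 1)
  g
}

.crossover_genomes <- function(a, b) {
  pick <- stats::runif(length(a)) < 0.5
  g <- a
  g[pick] <- b[pick]
  g
}

# apply the genome's preprocessor; returns selected column names
.genome_columns <- function(genome, X) {
  if (genome$preproc == "varfilter") {
    v <- apply(X, 2, stats::var)
    keep <- names(sort(v, decreasing = TRUE))[seq_len(max(1L, ceiling(ncol(X) / 2)))]
    keep[order(match(keep, colnames(X)))]
  } else colnames(X)
}

# fit the genome's model; returns scorer closure (continuous, oriented to
# carrier) and class-prediction closure
.genome_fit <- function(genome, X, y) {
  cols <- .genome_columns(genome, X)
  Xs <- X[, cols, drop = FALSE]
  y01 <- as.integer(y == "carrier")
  yf <- factor(y, c("wild_type", "carrier"))
  if (genome$model %in% c("logistic", "svm_rbf")) {
    fam <- genome$model
    if (fam == "svm_rbf") {
      st <- .std_fit(Xs)
      fit <- e1071::svm(.std_apply(Xs, st), yf, kernel = "radial",
                        cost = genome$cost, scale = FALSE)
      scorer <- function(Xn) {
        dv <- attr(stats::predict(fit, .std_apply(Xn[, cols, drop = FALSE], st),
                                  decision.values = TRUE), "decision.values")
        if (grepl("^carrier", colnames(dv)[1])) as.numeric(dv) else -as.numeric(dv)
      }
      list(scorer = scorer, classify = function(Xn)
        ifelse(scorer(Xn) >= 0, "carrier", "wild_type"))
    } else {
      sc <- .fit_scorer("logistic", Xs, y)
      scorer <- function(Xn) sc(Xn[, cols, drop = FALSE])
      list(scorer = scorer, classify = function(Xn)
        ifelse(scorer(Xn) >= 0.5, "carrier", "wild_type"))
    }
  } else if (genome$model == "boosted_trees") {
    cfg <- data.frame(max_depth = genome$depth, eta = genome$eta,
                      nrounds = genome$nrounds, subsample = 1)
    fit <- .fit_xgb(as.matrix(Xs), y01, cfg)
    scorer <- function(Xn)
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(Xn[, cols, drop = FALSE])))
    list(scorer = scorer, classify = function(Xn)
      ifelse(scorer(Xn) >= 0.5, "carrier", "wild_type"))
  } else {
    mtry <- max(1L, floor(genome$mtry_frac * length(cols)))
    fit <- randomForest::randomForest(as.matrix(Xs), yf,
                                      ntree = genome$ntree, mtry = mtry)
    scorer <- function(Xn)
      stats::predict(fit, as.matrix(Xn[, cols, drop = FALSE]),
                     type = "prob")[, "carrier"]
    list(scorer = scorer, classify = function(Xn)
      as.character(stats::predict(fit, as.matrix(Xn[, cols, drop = FALSE]))))
  }
}

.genome_cv_error <- function(genome, X, y, row_fold, folds) {
  errs <- vapply(seq_len(folds), function(f) {
    tr <- row_fold != f
    if (!any(!tr) || length(unique(y[tr])) < 2) return(NA_real_)
    fit <- tryCatch(.genome_fit(genome, X[tr, , drop = FALSE], y[tr]),
                    error = function(e) NULL)
    if (is.null(fit)) return(1)
    pred <- fit$classify(X[!tr, , drop = FALSE])
    mean(pred != y[!tr])
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

#' Genetic pipeline search (strategy D)
#'
#' Evolves (preprocessor, model, hyperparameter) genomes with tournament
#' selection, uniform crossover, per-gene mutation and single-genome
#' elitism; fitness is the patient-grouped 5-fold cross-validated
#' misclassification error. The best genome is refit on the full training
#' set. A deliberately small search: it preserves the computation (a
#' genetic algorithm minimizing grouped CV error) at desk scale.
#'
#' @param X training feature matrix (already pruned).
#' @param y training labels.
#' @param groups patient id per training row.
#' @param config a [ga_config()].
#' @param seed integer seed.
#' @return list: `genome`, `cv_error`, `history` (best fitness per
#'   generation, non-increasing), `scorer`, `cutoff`.
#' @export
fit_strategy_D <- function(X, y, groups, config = ga_config(), seed = 1L) {
  stopifnot(inherits(config, "ga_config"))
  X <- as.matrix(X)
  set.seed(seed)
  fold_of <- .patient_folds(groups, y, k = config$folds)
  row_fold <- fold_of[groups]
  pop <- replicate(config$population, .random_genome(), simplify = FALSE)
  eval_pop <- function(genomes) vapply(genomes, function(g)
    .genome_cv_error(g, X, y, row_fold, config$folds), numeric(1))
  fitness <- eval_pop(pop)
  history <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    elite_i <- which.min(fitness)
    newpop <- list(pop[[elite_i]])
    while (length(newpop) < config$population) {
      pick_parent <- function() {
        cand <- sample.int(length(pop), min(config$tournament, length(pop)))
        pop[[cand[which.min(fitness[cand])]]]
      }
      child <- pick_parent()
      if (stats::runif(1) < config$p_crossover)
        child <- .crossover_genomes(child, pick_parent())
      child <- .mutate_genome(child, config$p_mutation)
      newpop[[length(newpop) + 1]] <- child
    }
    new_fitness <- c(fitness[elite_i], eval_pop(newpop[-1]))
    pop <- newpop; fitness <- new_fitness
    history[gen] <- min(fitness)
  }
  best <- which.min(fitness)
  genome <- pop[[best]]
  final <- .genome_fit(genome, X, y)
  sc <- final$scorer(X)
  ry <- roc_youden(sc, y)
  list(genome = genome, cv_error = fitness[best], history = history,
       scorer = final$scorer, cutoff = ry$cutoff)
}
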