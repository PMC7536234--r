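# minimal feature table for split/strategy plumbing
toy_table <- function(n_patients = 8, images_each = 2, n_carrier = 4,
                      sep = 0, seed = 1) {
  set.seed(seed)
  pid <- rep(sprintf("P%02d", seq_len(n_patients)), each = images_each)
  lab <- rep(c(rep("carrier", n_carrier),
               rep("wild_type", n_patients - n_carrier)), each = images_each)
  n <- length(pid)
  data.frame(image_id = sprintf("I%03d", seq_len(n)),
             patient_id = pid, machine = "M", label = lab,
             f1 = rnorm(n) + sep * (lab == "carrier"),
             f2 = rnorm(n), f3 = rnorm(n),
             stringsAsFactors = FALSE)
}

test_that("the train/test split is per patient, stratified and reproducible", {
  tab <- toy_table(n_patients = 8, n_carrier = 4)
  sp <- split_patients(tab, 0.75, seed = 3)
  expect_length(sp$train, 6)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  # every image of a patient lands on one side
  side <- ifelse(tab$patient_id %in% sp$train, "tr", "te")
  expect_true(all(tapply(side, tab$patient_id,
                         function(s) length(unique(s))) == 1))

  big <- toy_table(n_patients = 100, n_carrier = 35, images_each = 1)
  sp1 <- split_patients(big, 0.75, seed = 9)
  sp2 <- split_patients(big, 0.75, seed = 9)
  expect_identical(sp1, sp2)
  carriers_tr <- sum(unique(big[big$patient_id %in% sp1$train,
                                c("patient_id", "label")])$label == "carrier")
  expect_equal(carriers_tr, round(0.75 * 35)) # stratified rounding

  degenerate <- toy_table(n_patients = 3, n_carrier = 1)
  expect_error(split_patients(degenerate), "split error")
})

test_that("Youden cutoff selection matches exhaustive enumeration", {
  r <- roc_youden(c(0.1, 0.2, 0.8, 0.9),
                  c("wild_type", "wild_type", "carrier", "carrier"))
  expect_equal(r$J, 1)
  expect_equal(r$cutoff, 0.8)

  r <- roc_youden(rep(0.5, 10), rep(c("carrier", "wild_type"), 5))
  expect_equal(r$J, 0)

  r <- roc_youden(c(0.1, 0.4, 0.35, 0.8),
                  c("wild_type", "wild_type", "carrier", "carrier"))
  expect_equal(r$J, 0.5)
  expect_equal(r$cutoff, 0.35) # tie with 0.8 broken by the lowest threshold

  # brute force over every candidate threshold on random score sets
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    sc <- round(runif(n), 2)
    lab <- sample(c("carrier", "wild_type"), n, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    r <- roc_youden(sc, lab)
    brute <- vapply(c(sort(unique(sc)), Inf), function(t) {
      pred <- ifelse(sc >= t, "carrier", "wild_type")
      cm <- confusion_matrix(pred, lab)
      cm$tp / (cm$tp + cm$fn) + cm$tn / (cm$tn + cm$fp) - 1
    }, numeric(1))
    expect_equal(r$J, max(brute))
  }
})

test_that("Cohen's kappa reproduces worked confusion matrices", {
  expect_equal(cohen_kappa(list(tp = 50, fp = 0, tn = 50, fn = 0))$kappa, 1)
  expect_equal(cohen_kappa(list(tp = 25, fp = 25, tn = 25, fn = 25))$kappa, 0)
  k <- cohen_kappa(list(tp = 40, fn = 10, fp = 20, tn = 30))
  expect_equal(k$po, 0.7)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.4)
  # degenerate all-one-cell table
  expect_equal(cohen_kappa(list(tp = 10, fp = 0, tn = 0, fn = 0))$kappa, 0)
})

test_that("kappa is invariant to relabeling both predictions and truth", {
  set.seed(2)
  pred <- sample(c("carrier", "wild_type"), 60, replace = TRUE)
  truth <- sample(c("carrier", "wild_type"), 60, replace = TRUE)
  flip <- function(x) ifelse(x == "carrier", "wild_type", "carrier")
  k1 <- cohen_kappa(confusion_matrix(pred, truth))$kappa
  k2 <- cohen_kappa(confusion_matrix(flip(pred), flip(truth),
                                     positive = "carrier"))$kappa
  expect_equal(k1, k2)
})

test_that("forward selection finds a perfect separator and terminates on noise", {
  set.seed(4)
  n <- 40
  y <- rep(c("carrier", "wild_type"), each = n / 2)
  X <- cbind(sep = ifelse(y == "carrier", 1, 0) + rnorm(n, sd = 0.01),
             n1 = rnorm(n), n2 = rnorm(n))
  fs <- forward_select("logistic", X, y)
  expect_equal(fs$selected[1], "sep")
  expect_equal(fs$kappa, 1)
  expect_equal(nrow(fs$trace), 1) # kappa cannot improve past 1

  # pure noise: terminates with a finite, non-empty trace
  Xn <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("z", 1:4)))
  fs <- forward_select("svm_rbf", Xn, y)
  expect_gte(length(fs$selected), 1)
  expect_lte(length(fs$selected), 4)
  expect_true(all(diff(c(-Inf, fs$trace$kappa)) > 0)) # strictly increasing
  expect_error(forward_select("logistic", X[, 0], y), "selection error")
})

test_that("grid search selects the CV-error argmin deterministically", {
  tab <- toy_table(n_patients = 16, n_carrier = 8, images_each = 2,
                   sep = 3, seed = 6)
  X <- tab[, c("f1", "f2", "f3")]
  grid <- expand.grid(max_depth = c(2L, 3L), eta = c(0.1, 0.3),
                      nrounds = 30L, subsample = 1.0)
  f1 <- fit_strategy_C(X, tab$label, tab$patient_id, grid = grid, seed = 5)
  f2 <- fit_strategy_C(X, tab$label, tab$patient_id, grid = grid, seed = 5)
  expect_equal(f1$config, f2$config)
  expect_equal(f1$cv_error, min(f1$cv_table$cv_error))
  expect_error(fit_strategy_C(X, tab$label, tab$patient_id,
                              grid = grid[0, ]), "config error")
})

test_that("feature gain concentrates on the informative feature", {
  tab <- toy_table(n_patients = 20, n_carrier = 10, images_each = 2,
                   sep = 4, seed = 8)
  X <- tab[, c("f1", "f2", "f3")]
  fit <- fit_strategy_C(X, tab$label, tab$patient_id,
                        grid = data.frame(max_depth = 2L, eta = 0.3,
                                          nrounds = 30L, subsample = 1.0),
                        seed = 2)
  g <- feature_gain(fit$model, colnames(X))
  expect_equal(g$feature[1], "f1")
  expect_equal(sum(g$gain), 1, tolerance = 1e-6)
  expect_true(all(g$gain >= 0))
})

test_that("the genetic search is elitist, deterministic and solves separable data", {
  tab <- toy_table(n_patients = 16, n_carrier = 8, images_each = 2,
                   sep = 5, seed = 10)
  X <- tab[, c("f1", "f2", "f3")]
  cfg <- ga_config(population = 8, generations = 4)
  d1 <- fit_strategy_D(X, tab$label, tab$patient_id, config = cfg, seed = 21)
  d2 <- fit_strategy_D(X, tab$label, tab$patient_id, config = cfg, seed = 21)
  expect_identical(d1$genome, d2$genome)
  expect_true(all(diff(d1$history) <= 0)) # best fitness never worsens
  expect_equal(d1$cv_error, 0, tolerance = 0.06) # near-separable data
  expect_error(ga_config(population = 1), "config error")
})

test_that("no patient crosses CV folds", {
  tab <- toy_table(n_patients = 20, n_carrier = 8, images_each = 3)
  set.seed(1)
  fold_of <- usradiomics:::.patient_folds(tab$patient_id, tab$label, k = 5)
  row_fold <- fold_of[tab$patient_id]
  expect_true(all(tapply(row_fold, tab$patient_id,
                         function(f) length(unique(f))) == 1))
  expect_equal(sort(unique(unname(fold_of))), 1:5)
})
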