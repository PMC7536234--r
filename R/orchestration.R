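#' Experiment configuration
#'
#' Bundles every stage's parameters. Exactly one of `cohort` (a
#' [cohort_spec()], simulated on the fly) or `manifest` (path to a
#' `manifest.csv` of DICOM pairs) must be given. The global seed propagates
#' to the split and to the stochastic strategies.
#'
#' @param cohort optional [cohort_spec()].
#' @param manifest optional manifest path.
#' @param r_threshold Pearson pruning cutoff (default 0.9).
#' @param alpha screening significance level (default 0.05).
#' @param train_fraction per-patient train fraction (default 0.75).
#' @param strategies subset of `c("A", "B", "C", "D")`.
#' @param per_machine also analyze each machine's subset (default TRUE).
#' @param Ng grey-level count (default 32).
#' @param xgb_grid strategy-C grid.
#' @param ga strategy-D [ga_config()].
#' @param seed global integer seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = NULL, manifest = NULL,
                              r_threshold = 0.9, alpha = 0.05,
                              train_fraction = 0.75,
                              strategies = c("A", "B", "C", "D"),
                              per_machine = TRUE, Ng = 32L,
                              xgb_grid = default_xgb_grid(),
                              ga = ga_config(), seed = 1L) {
  if (is.null(cohort) == is.null(manifest))
    stop("give exactly one of cohort or manifest")
  structure(list(cohort = cohort, manifest = manifest,
                 r_threshold = r_threshold, alpha = alpha,
                 train_fraction = train_fraction, strategies = strategies,
                 per_machine = per_machine, Ng = Ng, xgb_grid = xgb_grid,
                 ga = ga, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Screening summary table across datasets
#'
#' One row per dataset: features retained by the correlation pruning,
#' features significant in the univariate Wilcoxon screen, and the
#' significant count as a percentage of the retained count (one decimal).
#'
#' @param reports named list of screening results from [screen_features()].
#' @return data frame with columns `dataset`, `retained`, `significant`,
#'   `percent`.
#' @export
summarize_screening <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]$report
    data.frame(dataset = nm, retained = r$m, significant = r$observed,
               percent = r$percent, stringsAsFactors = FALSE)
  }))
}

#' Run the full experiment: simulate/extract, screen, split, classify
#'
#' Executes the pipeline end to end on the full dataset and (optionally)
#' each machine subset: feature extraction, correlation + Wilcoxon
#' screening, patient-level 75/25 split, and the configured classification
#' strategies. When `out_dir` is given, writes `features.csv`,
#' `screening_summary.csv`, `significant_features.csv`,
#' `strategy_metrics.csv` and `report.json`.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress stage logging (default TRUE).
#' @return list (report bundle): `features`, `screening` (per dataset),
#'   `screening_summary`, `significant`, `strategies` (per dataset),
#'   `metrics`, `config_echo`.
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(...)
  if (!is.null(config$cohort)) {
    say("simulate: ", config$cohort$n_patients, " patients")
    sim <- simulate_cohort(config$cohort)
    say("extract: ", length(sim$items), " images")
    features <- extract_cohort(sim, Ng = config$Ng)
  } else {
    man <- read_manifest(config$manifest)
    say("extract: ", nrow(man), " images")
    features <- extract_cohort(man, Ng = config$Ng)
  }
  datasets <- list(All = features)
  if (config$per_machine) {
    for (m in sort(unique(features$machine))) {
      sub <- features[features$machine == m, , drop = FALSE]
      # a machine subset is analyzable only with enough images and both classes
      if (nrow(sub) >= 3 && length(unique(sub$label)) == 2) {
        datasets[[m]] <- sub
      } else {
        say("skip machine ", m, ": too few images or one class only")
      }
    }
  }
  screening <- lapply(datasets, function(tab) {
    screen_features(tab, r_threshold = config$r_threshold,
                    alpha = config$alpha)
  })
  summary_tab <- summarize_screening(screening)
  say("screen: ", paste(summary_tab$dataset, summary_tab$retained,
                        collapse = "; "))
  significant <- do.call(rbind, lapply(names(screening), function(nm) {
    s <- screening[[nm]]
    sig <- s$report$significant
    if (!length(sig)) return(NULL)
    p <- sort(s$p_values[sig])
    data.frame(dataset = nm, feature = names(p), p_value = as.numeric(p),
               stringsAsFactors = FALSE)
  }))

  strat_results <- list(); metric_rows <- list()
  for (nm in if (length(config$strategies)) names(datasets) else character(0)) {
    tab <- datasets[[nm]]
    split <- split_patients(tab, train_fraction = config$train_fraction,
                            seed = config$seed)
    train <- tab[tab$patient_id %in% split$train, , drop = FALSE]
    test <- tab[tab$patient_id %in% split$test, , drop = FALSE]
    res <- list()
    for (st in config$strategies) {
      say("train ", nm, " strategy ", st)
      res[[st]] <- run_strategy(train, test, strategy = st,
                                r_threshold = config$r_threshold,
                                seed = config$seed,
                                xgb_grid = config$xgb_grid, ga = config$ga)
      metric_rows[[paste(nm, st)]] <- data.frame(
        dataset = nm, strategy = st,
        t(res[[st]]$train_metrics["accuracy"]),
        t(res[[st]]$test_metrics),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    strat_results[[nm]] <- res
  }
  metrics <- NULL
  if (length(metric_rows)) {
    metrics <- do.call(rbind, metric_rows)
    names(metrics)[3] <- "train_accuracy"
    rownames(metrics) <- NULL
  }

  bundle <- list(features = features, screening = screening,
                 screening_summary = summary_tab, significant = significant,
                 strategies = strat_results, metrics = metrics,
                 config_echo = list(r_threshold = config$r_threshold,
                                    alpha = config$alpha,
                                    train_fraction = config$train_fraction,
                                    seed = config$seed, Ng = config$Ng))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "screening_summary.csv"),
                     row.names = FALSE)
    if (!is.null(significant))
      utils::write.csv(significant,
                       file.path(out_dir, "significant_features.csv"),
                       row.names = FALSE)
    if (!is.null(metrics))
      utils::write.csv(metrics, file.path(out_dir, "strategy_metrics.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(screening_summary = summary_tab, metrics = metrics,
           config = bundle$config_echo),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
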