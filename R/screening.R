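#' Pearson-correlation redundancy pruning
#'
#' Removes all but one feature among groups of highly correlated features:
#' zero-variance columns are dropped first; then, while any pair exceeds the
#' threshold in absolute Pearson correlation, the pair with the largest |r|
#' is found and the member with the larger mean absolute correlation against
#' all remaining features is dropped (ties drop the later name in table
#' order). Every retained pair ends with |r| <= threshold, and pruning a
#' pruned table is a no-op.
#'
#' @param x data frame or matrix of feature columns (no metadata columns).
#' @param r_threshold Pearson cutoff, in (0, 1); default 0.9.
#' @return character vector of retained feature names, in original order.
#' @export
correlation_prune <- function(x, r_threshold = 0.9) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("insufficient data: need at least 3 rows")
  keep <- colnames(x)
  vars <- apply(x, 2, stats::var)
  keep <- keep[vars > 0]
  if (length(keep) < 2) return(keep)
  cm <- abs(stats::cor(x[, keep, drop = FALSE]))
  repeat {
    off <- cm
    diag(off) <- 0
    mx <- max(off)
    if (mx <= r_threshold) break
    hit <- which(off == mx, arr.ind = TRUE)[1, ]
    a <- rownames(cm)[hit[1]]; b <- colnames(cm)[hit[2]]
    mean_a <- mean(off[a, ]); mean_b <- mean(off[b, ])
    drop_name <- if (mean_a > mean_b) a
                 else if (mean_b > mean_a) b
                 else keep[max(match(c(a, b), keep))] # tie: later name
    keep <- setdiff(keep, drop_name)
    if (length(keep) < 2) break
    cm <- cm[keep, keep, drop = FALSE]
  }
  keep
}

#' Univariate Wilcoxon-Mann-Whitney screen
#'
#' Two-sided rank-sum test of each feature against the binary outcome:
#' exact enumeration when both groups have at most `exact_limit`
#' observations and the feature has no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x data frame or matrix of feature columns.
#' @param labels factor/character vector, two classes; the test is
#'   symmetric in the class coding.
#' @param exact_limit maximum group size for the exact test (default 25).
#' @return named numeric vector of p-values, one per feature column.
#' @export
wilcoxon_screen <- function(x, labels, exact_limit = 25L) {
  x <- as.matrix(x)
  cls <- unique(labels)
  if (length(cls) != 2)
    stop("screening error: need exactly two non-empty classes")
  g1 <- labels == cls[1]
  apply(x, 2, function(v) {
    if (length(unique(v)) == 1) return(1) # constant feature: no evidence
    a <- v[g1]; b <- v[!g1]
    exact <- length(a) <= exact_limit && length(b) <= exact_limit &&
      !anyDuplicated(c(a, b))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  })
}

#' Observed vs expected significant-test counts
#'
#' Summarizes a screening run the way a multiple-testing-aware univariate
#' analysis is reported: the number of significant features, the expected
#' number of type-I errors `m * alpha` among the `m` tested features, and
#' the observed percentage of significant tests.
#'
#' @param p_values named numeric vector of p-values.
#' @param alpha significance level (default 0.05).
#' @return list: `m`, `alpha`, `significant` (names), `observed`,
#'   `expected`, `percent` (observed as a percentage of `m`, one decimal).
#' @export
type1_report <- function(p_values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sig <- names(p_values)[p_values < alpha]
  m <- length(p_values)
  list(m = m, alpha = alpha, significant = sig,
       observed = length(sig), expected = m * alpha,
       percent = round(100 * length(sig) / m, 1))
}

#' Empirical size of the univariate screen under a null cohort
#'
#' Simulates a cohort whose two classes share one generative law
#' (`effect_size = 0`), extracts the full feature catalog once, then
#' repeatedly reassigns patient-level labels at random (prevalence 0.5) and
#' runs the per-feature Wilcoxon screen without pruning. The pooled
#' fraction of tests declared significant estimates the screen's type-I
#' error rate, to be compared with the nominal level.
#'
#' The per-image test is exactly calibrated only when images are
#' exchangeable across patients. Because a patient's images share a scanner,
#' a multi-machine cohort couples label permutations with inter-machine
#' feature shifts and inflates the rate; pass a machine-homogeneous
#' `cohort` (one-machine `machine_mix`) for a clean size check, mirroring
#' the per-machine analysis design.
#'
#' @param cohort a [cohort_spec()] with `effect_size = 0`.
#' @param n_perm number of label permutations (default 50).
#' @param alpha nominal significance level (default 0.05).
#' @param Ng grey-level count (default 32).
#' @param seed integer seed for the label permutations.
#' @return list: `rate` (pooled rejection fraction), `per_replicate`
#'   (rejection fraction per permutation), `n_tests`, `n_images`.
#' @export
null_rejection_rate <- function(cohort, n_perm = 50L, alpha = 0.05,
                                Ng = 32L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"), cohort$effect_size == 0)
  tab <- extract_cohort(simulate_cohort(cohort), Ng = Ng)
  feats <- as.matrix(tab[, setdiff(names(tab), c("image_id", "patient_id",
                                                 "machine", "label"))])
  patients <- unique(tab$patient_id)
  set.seed(seed)
  per <- vapply(seq_len(n_perm), function(i) {
    repeat {
      lab_p <- stats::setNames(
        sample(c("carrier", "wild_type"), length(patients), replace = TRUE),
        patients)
      if (length(unique(lab_p)) == 2) break
    }
    lab <- unname(lab_p[tab$patient_id])
    mean(wilcoxon_screen(feats, lab) < alpha)
  }, numeric(1))
  list(rate = mean(per), per_replicate = per,
       n_tests = n_perm * ncol(feats), n_images = nrow(tab))
}

#' Full screening stage: prune, test, report
#'
#' Applies [correlation_prune()] to the feature columns of a feature table,
#' tests the retained features with [wilcoxon_screen()], and assembles a
#' screening report. Optional Benjamini-Hochberg adjustment is available
#' but off by default: the analysis reports the expected type-I count
#' instead of correcting.
#'
#' @param table feature table from [extract_cohort()] (metadata columns
#'   `image_id`, `patient_id`, `machine`, `label` plus features).
#' @param r_threshold Pearson cutoff (default 0.9).
#' @param alpha significance level (default 0.05).
#' @param exact_limit exact-test group-size limit (default 25).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list: `retained`, `p_values`, `report` (from [type1_report()]).
#' @export
screen_features <- function(table, r_threshold = 0.9, alpha = 0.05,
                            exact_limit = 25L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  meta_cols <- c("image_id", "patient_id", "machine", "label")
  feats <- table[, setdiff(names(table), meta_cols), drop = FALSE]
  retained <- correlation_prune(feats, r_threshold)
  p <- wilcoxon_screen(feats[, retained, drop = FALSE], table$label,
                       exact_limit = exact_limit)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  list(retained = retained, p_values = p,
       report = type1_report(p, alpha))
}
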