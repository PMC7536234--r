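# shared fixtures built in code

# a discretized_roi straight from a level matrix (NA = outside); lets the
# matrix-based texture operations be tested on tiny hand grids that are
# below the ROI-size contract of roi_mask()
disc_grid <- function(levels, Ng = max(levels, na.rm = TRUE)) {
  levels <- matrix(as.integer(levels), nrow(levels), ncol(levels))
  structure(list(levels = levels, Ng = as.integer(Ng),
                 mask = !is.na(levels), pixel_spacing = c(1, 1)),
            class = "discretized_roi")
}

# a normalized_roi from a value matrix (NA = outside)
nroi_grid <- function(values, spacing = c(1, 1)) {
  structure(list(values = values, mask = !is.na(values),
                 pixel_spacing = spacing),
            class = "normalized_roi")
}

# frame + rectangular mask pair with given ROI values embedded in a larger
# image (pads so the mask passes its validity contract)
frame_with_roi <- function(values, spacing = c(1, 1), background = 0) {
  nr <- nrow(values); nc <- ncol(values)
  img <- matrix(background, nr + 4, nc + 4)
  img[3:(nr + 2), 3:(nc + 2)] <- values
  m <- matrix(FALSE, nr + 4, nc + 4)
  m[3:(nr + 2), 3:(nc + 2)] <- TRUE
  list(frame = us_frame(img, pixel_spacing = spacing),
       mask = roi_mask(m))
}

# brute-force symmetric co-occurrence counts by looping over all pixel pairs
brute_glcm <- function(levels, Ng, dr, dc) {
  cnt <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(levels))) for (c in seq_len(ncol(levels))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(levels) && c2 >= 1 && c2 <= ncol(levels) &&
        !is.na(levels[r, c]) && !is.na(levels[r2, c2])) {
      cnt[levels[r, c], levels[r2, c2]] <- cnt[levels[r, c], levels[r2, c2]] + 1
    }
  }
  cnt + t(cnt)
}

# brute-force runs along matrix rows (0 degrees) by explicit scanning
brute_runs_rows <- function(levels) {
  out <- list()
  for (r in seq_len(nrow(levels))) {
    run_val <- NA; run_len <- 0
    for (c in seq_len(ncol(levels) + 1)) {
      v <- if (c <= ncol(levels)) levels[r, c] else NA
      if (!is.na(v) && !is.na(run_val) && v == run_val) {
        run_len <- run_len + 1
      } else {
        if (!is.na(run_val)) out[[length(out) + 1]] <- c(run_val, run_len)
        run_val <- v; run_len <- 1
      }
    }
  }
  do.call(rbind, out)
}

# small in-memory cohort with caching so expensive fixtures are built once
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# cohort with a planted texture effect, features extracted once and shared
# by the recovery and invariant tests
effect_cohort_features <- function() {
  cached("effect_features", {
    cs <- cohort_spec(n_patients = 48, carrier_prevalence = 0.4,
                      images_per_patient = c(2L, 3L), effect_size = 2,
                      seed = 2024)
    extract_cohort(simulate_cohort(cs))
  })
}

# planted-feature table: the short-run high grey-level emphasis computed
# from phantom images (effect size 2) among pure-noise columns
planted_feature_table <- function(n_per_class = 75, n_noise = 20, seed = 1) {
  set.seed(seed)
  spec <- phantom_spec()
  mach <- default_machines()$Voluson
  srhge_of <- function(cl) {
    ph <- make_phantom(spec, mach, cl, effect_size = 2)
    disc <- discretize_roi(normalize_roi(ph$frame, ph$mask))
    glrlm(disc, 0L)$features[["srhge"]]
  }
  lab <- rep(c("carrier", "wild_type"), each = n_per_class)
  planted <- vapply(lab, srhge_of, numeric(1))
  noise <- matrix(stats::rnorm(2 * n_per_class * n_noise),
                  ncol = n_noise,
                  dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise))))
  df <- data.frame(planted = unname(planted), noise, check.names = FALSE)
  list(x = df, labels = lab)
}
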