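test_that("the default catalog has the documented family composition", {
  cat <- feature_catalog()
  counts <- table(cat$family)
  expect_equal(unname(counts[c("first_order", "morphology", "texture",
                               "fractal")]),
               c(20L, 14L, 183L, 15L), ignore_attr = TRUE)
  expect_equal(nrow(cat), 232L)
  expect_equal(anyDuplicated(cat$name), 0L)
})

test_that("first-order statistics match direct formula evaluation", {
  vals <- matrix(rep(c(0, 127.5, 255), length.out = 18), 3, 6)
  roi <- nroi_grid(vals)
  f <- first_order_features(roi)
  expect_equal(f[["F_stat.mean"]], mean(vals))
  expect_equal(f[["F_stat.range"]], 255)
  expect_equal(f[["F_stat.median"]], 127.5)

  roi <- nroi_grid(matrix(0, 4, 5)) # constant (post-normalization) ROI
  f <- first_order_features(roi)
  expect_equal(f[["F_stat.var"]], 0)
  expect_equal(f[["F_stat.skew"]], 0)
  expect_equal(f[["F_stat.kurt"]], 0)
  expect_equal(f[["F_stat.entropy"]], 0)
  expect_equal(f[["F_stat.uniformity"]], 1)
  expect_equal(f[["F_stat.cov"]], 0)

  vals <- matrix(rep(c(0, 0, 255, 255), 4), 4, 4)
  f <- first_order_features(nroi_grid(vals))
  expect_equal(f[["F_stat.energy"]], 8 * 255^2)
  expect_equal(f[["F_stat.rms"]], 255 / sqrt(2))
})

test_that("morphology matches analytic shapes", {
  rect <- matrix(TRUE, 10, 20)
  pad <- matrix(FALSE, 14, 24); pad[3:12, 3:22] <- TRUE
  f <- morphological_features(roi_mask(pad), spacing = c(1, 1))
  expect_equal(f[["F_morph.surface"]], 200)
  expect_equal(f[["F_morph.extent"]], 1.0)
  f <- morphological_features(roi_mask(pad), spacing = c(0.5, 0.5))
  expect_equal(f[["F_morph.surface"]], 50)

  disc <- matrix(FALSE, 48, 48)
  ctr <- 24.5
  for (r in 1:48) for (c in 1:48)
    disc[r, c] <- (r - ctr)^2 + (c - ctr)^2 <= 20^2
  f <- morphological_features(roi_mask(disc), spacing = c(1, 1))
  expect_equal(f[["L_major"]], f[["L_minor"]], tolerance = 0.05)
  expect_equal(f[["L_major"]], 40, tolerance = 0.05)
  expect_lt(f[["F_morph.ecc"]], 0.25)
  expect_equal(f[["F_morph.solidity"]], 1, tolerance = 0.05)
  expect_lte(f[["F_morph.solidity"]], 1)
  expect_equal(f[["F_morph.eq.diam"]], 40, tolerance = 0.05)
})

test_that("co-occurrence features match hand enumeration on tiny grids", {
  d <- disc_grid(matrix(1, 2, 2))
  f <- glcm(d, 1L)$features
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["joint.entr"]], 0)

  d <- disc_grid(matrix(c(1, 1, 2, 2), 2, 2)) # columns (1,1) and (2,2)
  g <- glcm(d, 1L, directions = "0")
  expect_equal(g$P[1, 2], 0.5)
  expect_equal(g$P[2, 1], 0.5)
  expect_equal(g$features[["contrast"]], 1)
  expect_equal(g$features[["energy"]], 0.5)
})

test_that("co-occurrence matrices agree with brute-force pair enumeration", {
  set.seed(99)
  offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                  `90` = c(-1L, 0L), `135` = c(1L, 1L))
  for (rep_i in 1:5) {
    lev <- matrix(sample(1:4, 16, replace = TRUE), 4, 4)
    lev[sample(16, 3)] <- NA # irregular mask
    d <- disc_grid(lev, Ng = 4L)
    for (dir in names(offsets)) {
      got <- usradiomics:::.glcm_counts(d$levels, 4L, offsets[[dir]], 1L)
      want <- brute_glcm(lev, 4L, offsets[[dir]][1], offsets[[dir]][2])
      expect_equal(got, want, ignore_attr = TRUE)
    }
    # merged matrix is the normalized pooled count matrix, sums to 1
    P <- glcm(d, 1L, "merged")$P
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
})

test_that("run-length features match run enumeration", {
  d <- disc_grid(matrix(c(1, 1, 1, 2), 1, 4))
  g <- glrlm(d, 0L)
  expect_equal(g$R[1, 3], 1)
  expect_equal(g$R[2, 1], 1)
  expect_equal(g$Nr, 2)
  expect_equal(g$features[["sre"]], (1 / 9 + 1) / 2, tolerance = 1e-12)
  expect_equal(g$features[["lre"]], 5)

  d <- disc_grid(matrix(1, 1, 7))
  g <- glrlm(d, 0L)
  expect_equal(g$Nr, 1)
  expect_equal(g$features[["sre"]], 1 / 49)
  expect_equal(g$features[["run.pct"]], 1 / 7)

  d <- disc_grid(matrix(c(1, 2, 1, 2), 1, 4))
  g <- glrlm(d, 0L)
  expect_equal(g$Nr, 4)
  expect_equal(g$features[["sre"]], 1)
  expect_equal(g$features[["lre"]], 1)
})

test_that("run-length scanning equals brute-force row scanning on random grids", {
  set.seed(41)
  for (rep_i in 1:5) {
    lev <- matrix(sample(1:3, 20, replace = TRUE), 4, 5)
    lev[sample(20, 4)] <- NA
    d <- disc_grid(lev, Ng = 3L)
    g <- glrlm(d, 0L) # 0 degrees = horizontal scanning along each row
    runs <- brute_runs_rows(lev)
    want <- matrix(0, 3, max(runs[, 2]))
    for (k in seq_len(nrow(runs)))
      want[runs[k, 1], runs[k, 2]] <- want[runs[k, 1], runs[k, 2]] + 1
    expect_equal(g$R[, seq_len(ncol(want)), drop = FALSE], want,
                 ignore_attr = TRUE)
    expect_equal(sum(g$R[g$R > 0] %% 1), 0) # integer counts
  }
})

test_that("size-zone features match connected-component enumeration", {
  d <- disc_grid(matrix(c(1, 2, 1, 3), 2, 2)) # zones: {1,1}(size 2 is wrong?)
  # levels: [,1] = (1,2); [,2] = (1,3) -> zone level 1 of size 2 (column-adjacent)
  g <- glszm(d)
  expect_equal(g$Nz, 3)
  expect_equal(g$features[["sze"]], (1 / 4 + 1 + 1) / 3)

  d <- disc_grid(matrix(1, 3, 4))
  g <- glszm(d)
  expect_equal(g$Nz, 1)
  expect_equal(g$features[["z.pct"]], 1 / 12)

  d <- disc_grid(matrix(1:6, 2, 3))
  g <- glszm(d)
  expect_equal(g$features[["sze"]], 1)
  expect_equal(g$features[["lze"]], 1)
})

test_that("distance-zone summaries follow the city-block border distance", {
  # single zone touching the border
  d <- disc_grid(matrix(1, 3, 5))
  f <- distance_zone_features(d)
  expect_equal(f[["sde"]], 1)
  expect_equal(f[["zd.entr"]], 0)

  # centre pixel of a 3x5 grid is its own zone at distance 2
  lev <- matrix(1, 3, 5); lev[2, 3] <- 2
  f <- distance_zone_features(disc_grid(lev))
  expect_equal(f[["sde"]], (1 + 1 / 4) / 2)
  expect_equal(f[["lde"]], (1 + 4) / 2)
})

test_that("pixel counts are conserved by run and zone matrices", {
  set.seed(7)
  ph <- make_phantom(phantom_spec(), default_machines()$Esaote, "wild_type")
  d <- discretize_roi(normalize_roi(ph$frame, ph$mask))
  np <- sum(d$mask)
  for (dir in c(0L, 45L, 90L, 135L)) {
    g <- glrlm(d, dir)
    expect_equal(sum(col(g$R) * g$R), np)
  }
  s <- glszm(d)
  expect_equal(sum(col(s$S) * s$S), np)
})

test_that("rotating the grid by 90 degrees permutes directional run features", {
  set.seed(55)
  lev <- matrix(sample(1:4, 64, replace = TRUE), 8, 8)
  d <- disc_grid(lev, 4L)
  rot <- t(lev)[nrow(t(lev)):1, ] # counter-clockwise 90-degree rotation
  dr <- disc_grid(rot, 4L)
  expect_equal(glrlm(d, 0L)$features, glrlm(dr, 90L)$features)
  expect_equal(glrlm(d, 90L)$features, glrlm(dr, 0L)$features)
  expect_equal(glrlm(d, 45L)$features, glrlm(dr, 135L)$features)
  expect_equal(glrlm(d, 135L)$features, glrlm(dr, 45L)$features)
  # direction-averaged co-occurrence features are rotation-invariant
  expect_equal(glcm(d, 1L, "average")$features,
               glcm(dr, 1L, "average")$features)
  expect_equal(glcm(d, 1L, "merged")$features,
               glcm(dr, 1L, "merged")$features)
})

test_that("box counting recovers known dimensions", {
  full <- box_count_fd(nroi_grid(matrix(255, 8, 8)), 0.5)
  expect_equal(full$counts, c(64L, 16L, 4L, 1L))
  expect_equal(full$fd, 2)

  one <- matrix(0, 8, 8); one[4, 5] <- 255
  single <- box_count_fd(nroi_grid(one), 0.5)
  expect_equal(single$fd, 0)

  line <- matrix(0, 8, 8); line[3, ] <- 255
  lf <- box_count_fd(nroi_grid(line), 0.5)
  expect_equal(lf$counts, c(8L, 4L, 2L, 1L))
  expect_equal(lf$fd, 1)

  empty <- box_count_fd(nroi_grid(matrix(0, 8, 8)), 0.5)
  expect_equal(empty$fd, 0)
  expect_true(empty$degenerate)
})

test_that("extraction returns the full catalog with defined fallbacks", {
  set.seed(12)
  ph <- make_phantom(phantom_spec(), default_machines()$Voluson, "carrier",
                     effect_size = 1)
  fv <- extract_all(ph$frame, ph$mask)
  expect_identical(names(fv), feature_catalog()$name)
  expect_true(all(is.finite(fv)))

  # constant-intensity ellipse: entropies 0, energies 1, vector complete
  const <- us_frame(matrix(100, 128, 128), ph$frame$pixel_spacing)
  fv <- extract_all(const, ph$mask)
  expect_identical(names(fv), feature_catalog()$name)
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["F_cm.joint.entr"]), 0)
  expect_equal(unname(fv["F_cm.energy"]), 1)
  expect_equal(unname(fv["F_szm.z.entr"]), 0)
  expect_equal(unname(fv["F_stat.entropy"]), 0)
})
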