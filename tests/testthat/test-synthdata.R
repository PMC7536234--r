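spec <- phantom_spec()
mach <- default_machines()

test_that("class label enters the generative law only through the effect", {
  # effect 0: carrier and wild-type draws are identical at the same RNG state
  set.seed(10)
  a <- make_phantom(spec, mach$Voluson, "carrier", effect_size = 0)
  set.seed(10)
  b <- make_phantom(spec, mach$Voluson, "wild_type", effect_size = 0)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$mask$mask, b$mask$mask)

  # zero spot boost: classes share the law even at positive effect size
  spec0 <- phantom_spec(spot_boost = 0)
  set.seed(11)
  a <- make_phantom(spec0, mach$Voluson, "carrier", effect_size = 2)
  set.seed(11)
  b <- make_phantom(spec0, mach$Voluson, "wild_type", effect_size = 2)
  expect_identical(a$frame$pixels, b$frame$pixels)
})

test_that("an ellipse that cannot fit the image is rejected", {
  big <- phantom_spec(image_size = 64, ellipse_axes = c(30, 40))
  set.seed(1)
  expect_error(make_phantom(big, mach$Voluson), "does not fit")
})

test_that("machine transform is the documented monotone mapping", {
  fr <- function(v) us_frame(matrix(v, 8, 8))
  ident <- machine_profile("id", gamma = 1, gain = 1, noise_floor = 0)
  expect_equal(apply_machine_transform(fr(123), ident)$pixels,
               matrix(123, 8, 8))
  hot <- machine_profile("hot", gain = 2)
  expect_equal(apply_machine_transform(fr(255), hot)$pixels,
               matrix(255, 8, 8)) # clipped
  sq <- machine_profile("sq", gamma = 0.5)
  expect_equal(apply_machine_transform(fr(64), sq)$pixels[1, 1],
               255 * sqrt(64 / 255), tolerance = 1e-12)
  # monotone on a grey ramp
  ramp <- us_frame(matrix(0:255, 16, 16))
  out <- apply_machine_transform(ramp, mach$Toshiba)$pixels
  expect_true(all(diff(as.vector(out)[1:256]) >= 0))
  expect_equal(apply_machine_transform(ramp, mach$Samsung)$tags$machine,
               "Samsung")
})

test_that("cohort manifest has the promised shape and label behaviour", {
  cs <- cohort_spec(n_patients = 8, images_per_patient = c(2L, 2L), seed = 5)
  out <- withr::local_tempdir()
  man <- make_cohort(cs, out)
  expect_equal(nrow(man), 16L)
  expect_equal(length(unique(man$patient_id)), 8L)
  expect_setequal(names(man), c("image_id", "path_image", "path_mask",
                                "machine", "patient_id", "side", "plane",
                                "label"))
  expect_true(all(file.exists(man$path_image), file.exists(man$path_mask)))
  # hierarchical layout <machine>/<patient>/<side>/<plane>/
  rel <- sub(paste0("^", out, "/?"), "", man$path_image[1])
  expect_match(rel, "^[A-Za-z]+/P[0-9]+/(left|right)/(longitudinal|coronal)/original\\.dcm$")

  all_carrier <- simulate_cohort(cohort_spec(n_patients = 5,
                                             carrier_prevalence = 1,
                                             seed = 2))
  expect_true(all(all_carrier$manifest$label == "carrier"))
})

test_that("carrier counts follow the binomial law and are reproducible", {
  cs <- cohort_spec(n_patients = 100, carrier_prevalence = 0.35, seed = 77)
  sim1 <- simulate_cohort(cs)
  sim2 <- simulate_cohort(cs)
  pat <- unique(sim1$manifest[, c("patient_id", "label")])
  k <- sum(pat$label == "carrier")
  expect_gte(k, qbinom(0.005, 100, 0.35))
  expect_lte(k, qbinom(0.995, 100, 0.35))
  expect_identical(sim1$manifest, sim2$manifest)
  # labels constant within patient
  expect_true(all(tapply(sim1$manifest$label, sim1$manifest$patient_id,
                         function(l) length(unique(l))) == 1))
})

test_that("identical cohort specs write byte-identical DICOM trees", {
  cs <- cohort_spec(n_patients = 4, images_per_patient = c(1L, 2L), seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- make_cohort(cs, d1); m2 <- make_cohort(cs, d2)
  expect_identical(unname(tools::md5sum(sort(m1$path_image))),
                   unname(tools::md5sum(sort(m2$path_image))))
  expect_identical(unname(tools::md5sum(sort(m1$path_mask))),
                   unname(tools::md5sum(sort(m2$path_mask))))
})

test_that("the planted class gap in short-run high grey-level emphasis grows with effect size", {
  srhge_median_gap <- function(effect, n = 100) {
    gap_of <- function(cl) {
      vapply(seq_len(n), function(i) {
        ph <- make_phantom(spec, mach$Voluson, cl, effect_size = effect)
        disc <- discretize_roi(normalize_roi(ph$frame, ph$mask))
        glrlm(disc, 0L)$features[["srhge"]]
      }, numeric(1))
    }
    median(gap_of("carrier")) - median(gap_of("wild_type"))
  }
  set.seed(1234)
  gaps <- vapply(c(0, 1, 2), srhge_median_gap, numeric(1))
  expect_true(all(diff(gaps) >= 0))
  expect_gt(gaps[3], gaps[1])
})
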