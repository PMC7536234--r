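#' Phantom generation parameters
#'
#' Parameters of a single synthetic ovary phantom: an elliptical
#' region of interest filled with multiplicative Rayleigh speckle over a
#' piecewise-constant echogenicity map, optional dark circular follicles
#' (class-independent nuisance structure), and bright spots whose rate and
#' amplitude carry the plantable class effect.
#'
#' @param image_size square image side, pixels.
#' @param pixel_spacing default spacing, mm/pixel (overridden by a machine
#'   profile when one is supplied to [make_phantom()]).
#' @param ellipse_axes semi-axis range, mm (min, max).
#' @param echogenicity_base mean grey level inside the ovary (0-255 scale).
#' @param background_grey mean grey level outside the ovary.
#' @param speckle_scale speckle blend weight in `[0, 1]`: 0 gives a noiseless
#'   echo map, 1 fully developed Rayleigh speckle (multiplicative, unit mean).
#' @param follicle_count range of dark circular inclusions per phantom.
#' @param spot_rate expected bright-spot count per 100 ROI pixels
#'   (wild-type class; carriers receive `spot_rate * (1 + effect_size)`).
#' @param spot_boost additive grey increment at spot pixels (scaled the same
#'   way for carriers).
#' @param spot_size spot diameter range, pixels.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         pixel_spacing = 0.30,
                         ellipse_axes = c(8, 15),
                         echogenicity_base = 110,
                         background_grey = 40,
                         speckle_scale = 0.5,
                         follicle_count = c(0L, 3L),
                         spot_rate = 1.0,
                         spot_boost = 60,
                         spot_size = c(1L, 3L)) {
  stopifnot(image_size >= 32, pixel_spacing > 0,
            length(ellipse_axes) == 2, all(ellipse_axes > 0),
            ellipse_axes[1] <= ellipse_axes[2],
            speckle_scale >= 0, speckle_scale <= 1,
            spot_rate >= 0, spot_boost >= 0,
            all(spot_size >= 1))
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing,
                 ellipse_axes = ellipse_axes,
                 echogenicity_base = echogenicity_base,
                 background_grey = background_grey,
                 speckle_scale = speckle_scale,
                 follicle_count = as.integer(follicle_count),
                 spot_rate = spot_rate,
                 spot_boost = spot_boost,
                 spot_size = as.integer(spot_size)),
            class = "phantom_spec")
}

#' Scanner profile: a monotone intensity transform plus pixel spacing
#'
#' Emulates inter-machine heterogeneity as a monotone grey-level mapping
#' `clip(gain * 255 * (g/255)^gamma + noise_floor)` and a machine-specific
#' pixel spacing.
#'
#' @param name machine label.
#' @param gamma intensity exponent, > 0.
#' @param gain multiplicative contrast, > 0.
#' @param noise_floor additive grey offset.
#' @param pixel_spacing mm/pixel.
#' @return object of class `machine_profile`.
#' @export
machine_profile <- function(name, gamma = 1, gain = 1, noise_floor = 0,
                            pixel_spacing = 0.15) {
  stopifnot(gamma > 0, gain > 0, pixel_spacing > 0)
  structure(list(name = name, gamma = gamma, gain = gain,
                 noise_floor = noise_floor, pixel_spacing = pixel_spacing),
            class = "machine_profile")
}

#' Default set of four scanner profiles
#'
#' Mild, monotone intensity differences and distinct pixel spacings for the
#' four scanner makes in the study design.
#'
#' @return named list of [machine_profile()] objects.
#' @export
default_machines <- function() {
  list(
    Voluson = machine_profile("Voluson", gamma = 1.00, gain = 1.00,
                              noise_floor = 0, pixel_spacing = 0.30),
    Toshiba = machine_profile("Toshiba", gamma = 0.90, gain = 1.05,
                              noise_floor = 4, pixel_spacing = 0.36),
    Samsung = machine_profile("Samsung", gamma = 1.10, gain = 0.95,
                              noise_floor = 2, pixel_spacing = 0.32),
    Esaote  = machine_profile("Esaote",  gamma = 1.00, gain = 1.10,
                              noise_floor = 6, pixel_spacing = 0.40)
  )
}

#' Cohort-level generation parameters
#'
#' @param n_patients number of patients.
#' @param carrier_prevalence fraction of carrier patients in (0, 1].
#' @param images_per_patient integer range (min, max), at most 4.
#' @param machine_mix named numeric vector of per-machine patient proportions
#'   (names must match `machines`); must sum to 1.
#' @param effect_size scalar >= 0 scaling the carrier-class spot rate and
#'   boost; 0 makes the two class-conditional laws identical.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @param phantom a [phantom_spec()].
#' @param machines list of [machine_profile()]s.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100L,
                        carrier_prevalence = 1 / 3,
                        images_per_patient = c(1L, 4L),
                        machine_mix = NULL,
                        effect_size = 1,
                        seed = 1L,
                        phantom = phantom_spec(),
                        machines = default_machines()) {
  if (is.null(machine_mix)) {
    machine_mix <- rep(1 / length(machines), length(machines))
    names(machine_mix) <- names(machines)
  }
  stopifnot(n_patients >= 1,
            carrier_prevalence > 0, carrier_prevalence <= 1,
            images_per_patient[1] >= 1, images_per_patient[2] <= 4,
            images_per_patient[1] <= images_per_patient[2],
            abs(sum(machine_mix) - 1) < 1e-8,
            all(names(machine_mix) %in% names(machines)),
            effect_size >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 carrier_prevalence = carrier_prevalence,
                 images_per_patient = as.integer(images_per_patient),
                 machine_mix = machine_mix,
                 effect_size = effect_size,
                 seed = as.integer(seed),
                 phantom = phantom,
                 machines = machines),
            class = "cohort_spec")
}

#' Apply a scanner intensity transform to a frame
#'
#' `output = clip(gain * 255 * (input/255)^gamma + noise_floor, 0, 255)`,
#' a monotone mapping; the frame's machine tag and pixel spacing are updated.
#'
#' @param frame a `us_frame` (see [us_frame()]).
#' @param machine a [machine_profile()].
#' @return transformed `us_frame`.
#' @export
apply_machine_transform <- function(frame, machine) {
  stopifnot(inherits(frame, "us_frame"), inherits(machine, "machine_profile"))
  p <- frame$pixels
  out <- .clip255(machine$gain * 255 * (p / 255)^machine$gamma + machine$noise_floor)
  frame$pixels <- out
  frame$tags$machine <- machine$name
  frame
}

# draw a filled ellipse mask; centre/axes in pixels, theta in radians
.ellipse_mask <- function(n, cr, cc, a, b, theta) {
  rr <- matrix(seq_len(n), n, n) - cr
  cc_ <- matrix(seq_len(n), n, n, byrow = TRUE) - cc
  u <- rr * cos(theta) + cc_ * sin(theta)
  v <- -rr * sin(theta) + cc_ * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

.disc_mask <- function(n, cr, cc, radius) {
  rr <- matrix(seq_len(n), n, n) - cr
  cc_ <- matrix(seq_len(n), n, n, byrow = TRUE) - cc
  rr^2 + cc_^2 <= radius^2
}

#' Generate one phantom image/mask pair
#'
#' Renders an elliptical ovary with optional follicles, plants bright spots
#' (rate and amplitude inflated by `1 + effect_size` for carriers), applies
#' multiplicative Rayleigh speckle and the machine transform, and quantizes
#' to 8 bits. The class label enters the generative law only through the
#' spot parameters, so `effect_size = 0` makes the two classes exchangeable.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param spec a [phantom_spec()].
#' @param machine a [machine_profile()].
#' @param class `"carrier"` or `"wild_type"`.
#' @param effect_size scalar >= 0.
#' @return list with `frame` (`us_frame`), `mask` (`roi_mask`) and `truth`
#'   (patient-free ground-truth record: class and realized spot parameters).
#' @export
make_phantom <- function(spec, machine = default_machines()[[1]],
                         class = c("wild_type", "carrier"),
                         effect_size = 0) {
  stopifnot(inherits(spec, "phantom_spec"), effect_size >= 0)
  class <- match.arg(class)
  n <- spec$image_size
  sp <- machine$pixel_spacing
  ax_mm <- stats::runif(2, spec$ellipse_axes[1], spec$ellipse_axes[2])
  a <- max(ax_mm) / sp; b <- min(ax_mm) / sp # semi-axes, pixels
  if (a > n / 2 - 3)
    stop("ellipse does not fit inside the image at this pixel spacing")
  theta <- stats::runif(1, 0, pi)
  jit <- max(0, n / 2 - a - 3)
  cr <- n / 2 + stats::runif(1, -1, 1) * min(jit, n / 10)
  cc <- n / 2 + stats::runif(1, -1, 1) * min(jit, n / 10)
  ell <- .ellipse_mask(n, cr, cc, a, b, theta)

  echo <- matrix(spec$background_grey, n, n)
  echo[ell] <- spec$echogenicity_base

  # follicles: interior dark discs, removed from the ROI mask
  nf <- .resample(seq(spec$follicle_count[1], spec$follicle_count[2]), 1)
  fol <- matrix(FALSE, n, n)
  if (nf > 0) {
    for (k in seq_len(nf)) {
      # centre at <= 0.55 of the normalized radius keeps the mask connected
      rho <- sqrt(stats::runif(1)) * 0.55
      phi <- stats::runif(1, 0, 2 * pi)
      fr <- cr + rho * a * cos(phi) * cos(theta) - rho * b * sin(phi) * sin(theta)
      fc <- cc + rho * a * cos(phi) * sin(theta) + rho * b * sin(phi) * cos(theta)
      frad <- min(stats::runif(1, 1.5, 3.5), 0.30 * min(a, b))
      fol <- fol | .disc_mask(n, fr, fc, frad)
    }
    fol <- fol & ell
    echo[fol] <- spec$echogenicity_base * 0.3
  }
  mask <- ell & !fol
  # overlapping follicles can pinch off single-pixel slivers; keep the main
  # component so the mask honors its one-component contract
  lab <- .label4(mask)
  if (max(lab) > 1) mask <- lab == which.max(tabulate(lab[lab > 0]))

  # planted class effect: bright spots, scaled by (1 + effect_size) for carriers
  eff <- if (class == "carrier") effect_size else 0
  rate <- spec$spot_rate * (1 + eff)
  boost <- spec$spot_boost * (1 + eff)
  npx <- sum(mask)
  nspots <- stats::rpois(1, rate * npx / 100)
  if (nspots > 0 && boost > 0) {
    idx <- .resample(which(mask), min(nspots, npx))
    diam <- .resample(seq(spec$spot_size[1], spec$spot_size[2]),
                      length(idx), replace = TRUE)
    for (k in seq_along(idx)) {
      r0 <- (idx[k] - 1) %% n + 1; c0 <- (idx[k] - 1) %/% n + 1
      if (diam[k] <= 1) {
        echo[r0, c0] <- echo[r0, c0] + boost
      } else {
        sm <- .disc_mask(n, r0, c0, diam[k] / 2) & mask
        echo[sm] <- echo[sm] + boost
      }
    }
  }

  # fully developed speckle: unit-mean Rayleigh field, blended by speckle_scale
  ray <- sqrt(-2 * log(stats::runif(n * n))) / sqrt(pi / 2)
  field <- (1 - spec$speckle_scale) + spec$speckle_scale * matrix(ray, n, n)
  img <- .clip255(echo * field)

  frame <- us_frame(img, pixel_spacing = c(sp, sp),
                    tags = list(machine = machine$name, patient_id = NA_character_,
                                side = "left", plane = "longitudinal"))
  frame <- apply_machine_transform(frame, machine)
  frame$pixels <- round(frame$pixels)
  truth <- list(class = class,
                planted = list(n_spots = nspots, boost = boost, rate = rate))
  list(frame = frame, mask = roi_mask(mask), truth = truth)
}

#' Simulate a cohort in memory
#'
#' Same generative process as [make_cohort()] but without touching disk:
#' returns the phantom image/mask pairs and the manifest-shaped metadata
#' table. Deterministic in the spec (including its seed).
#'
#' @param cohort a [cohort_spec()].
#' @return list with `items` (each: `frame`, `mask`, `truth`) and
#'   `manifest` (data frame without path columns).
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$seed)
  machines <- cohort$machines
  mix <- cohort$machine_mix
  combos <- expand.grid(side = c("left", "right"),
                        plane = c("longitudinal", "coronal"),
                        stringsAsFactors = FALSE)
  rows <- list(); items <- list(); img_i <- 0L
  for (p in seq_len(cohort$n_patients)) {
    pid <- sprintf("P%03d", p)
    mach_name <- sample(names(mix), 1, prob = mix)
    machine <- machines[[mach_name]]
    label <- if (stats::runif(1) < cohort$carrier_prevalence) "carrier" else "wild_type"
    n_img <- .resample(seq(cohort$images_per_patient[1], cohort$images_per_patient[2]), 1)
    views <- combos[sample(nrow(combos), n_img), , drop = FALSE]
    for (j in seq_len(n_img)) {
      img_i <- img_i + 1L
      ph <- make_phantom(cohort$phantom, machine, class = label,
                         effect_size = cohort$effect_size)
      ph$frame$tags$patient_id <- pid
      ph$frame$tags$side <- views$side[j]
      ph$frame$tags$plane <- views$plane[j]
      ph$truth$patient_id <- pid
      items[[img_i]] <- ph
      rows[[img_i]] <- data.frame(image_id = sprintf("I%04d", img_i),
                                  machine = mach_name, patient_id = pid,
                                  side = views$side[j], plane = views$plane[j],
                                  label = label, stringsAsFactors = FALSE)
    }
  }
  list(items = items, manifest = do.call(rbind, rows))
}

#' Generate a synthetic cohort and write it as DICOM files plus a manifest
#'
#' Draws patient labels at the configured prevalence, assigns each patient a
#' machine and 1-4 views (unique side/plane combinations), writes one
#' original + one mask DICOM per image under
#' `<machine>/<patient>/<side>/<plane>/`, and writes `manifest.csv`.
#' Identical specs (including the seed) yield byte-identical output.
#'
#' @param cohort a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data frame, invisibly; columns `image_id`,
#'   `path_image`, `path_mask`, `machine`, `patient_id`, `side`, `plane`,
#'   `label`.
#' @export
make_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  sim <- simulate_cohort(cohort)
  man <- sim$manifest
  man$path_image <- NA_character_; man$path_mask <- NA_character_
  for (i in seq_len(nrow(man))) {
    leaf <- file.path(out_dir, man$machine[i], man$patient_id[i],
                      man$side[i], man$plane[i])
    dir.create(leaf, recursive = TRUE, showWarnings = FALSE)
    ph <- sim$items[[i]]
    pi_path <- file.path(leaf, "original.dcm")
    pm_path <- file.path(leaf, "mask.dcm")
    write_dicom(ph$frame$pixels, pi_path,
                pixel_spacing = ph$frame$pixel_spacing, tags = ph$frame$tags)
    write_dicom(matrix(ifelse(ph$mask$mask, 255L, 0L), nrow(ph$mask$mask)),
                pm_path, pixel_spacing = ph$frame$pixel_spacing,
                tags = ph$frame$tags)
    man$path_image[i] <- pi_path; man$path_mask[i] <- pm_path
  }
  man <- man[, c("image_id", "path_image", "path_mask", "machine",
                 "patient_id", "side", "plane", "label")]
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
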