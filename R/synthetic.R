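# Default per-response effect structure of the generator, log scale.
# Female effects mirror the additive-model coefficient pattern of the study
# cohort (signs and magnitudes); male effects are modest centered-scale
# main effects plus an interaction, qualitatively matching the male
# interaction-model results. Responses here are the eight GENERATED base
# measures; the three shape indices are derived as AP/ML afterwards.
.default_effects <- function() {
  tibble(
    response = c("IAP", "IML", "MAP", "MML", "OAP", "OML", "theta_a", "theta_b"),
    beta_gv_female     = c(0.029, 0.074, 0.038, 0.059, 0.071, 0.024, -0.11, 0.26),
    beta_weight_female = c(0.032, 0.030, 0.130, -0.075, 0.160, -0.110, -0.099, 0.16),
    beta_gv_male       = c(0.04, -0.03, 0.01, -0.05, -0.01, -0.02, 0.01, -0.01),
    beta_weight_male   = c(0.05, -0.04, 0.01, -0.06, -0.01, -0.03, 0.01, -0.01),
    beta_interaction_male = c(0.10, -0.10, 0.00, -0.10, 0.00, 0.00, 0.00, 0.00),
    resid_sd = rep(0.08, 8)
  )
}

# per-sex mean canal template (mm / degrees); female canal roomier, as in
# human pelves
.default_templates <- function() {
  list(
    male   = c(IAP = 105, IML = 123, MAP = 110, MML = 95,  OAP = 110, OML = 105,
               theta_a = 72, theta_b = 60),
    female = c(IAP = 115, IML = 128, MAP = 120, MML = 105, OAP = 118, OML = 115,
               theta_a = 80, theta_b = 62)
  )
}

#' Generator configuration
#'
#' Parameters of the synthetic cohort generator. Defaults encode the
#' statistical structure of the study cohort: per-sex body-weight and
#' female gut-volume marginals matching the published descriptive
#' statistics; male gut volume scaling with negative allometry on body
#' weight (log GV = a + b log W + noise with b < 1, the intercept solved
#' so the male GV mean matches its target); female gut volume independent
#' of weight; linear effects of log GV and log weight (plus a male
#' interaction) on each log canal measure; and observer noise that is
#' larger on the "fuzzy" ischial-tuberosity landmarks that define the
#' outlet ML diameter.
#'
#' @param n_male,n_female Specimens per sex (study sizes 44 and 48).
#' @param seed Integer seed; every simulation function sets it, so a fixed
#'   config reproduces bit-identical output.
#' @param weight_mean_male,weight_sd_male Male body-weight normal (kg).
#' @param weight_mean_female,weight_sd_female Female body-weight normal (kg).
#' @param stature_mean_male,stature_sd_male,stature_mean_female,stature_sd_female
#'   Stature normals (m).
#' @param gv_mean_female,gv_sd_female Female gut-volume normal (cc),
#'   independent of weight.
#' @param gv_mean_male Target male mean gut volume (cc).
#' @param allometry_b Male allometric exponent of GV on weight (0 < b < 1
#'   encodes negative allometry; default 0.8).
#' @param gv_log_sd_male Residual SD of male log GV around the allometric
#'   line (default 0.15, matching the male GV coefficient of variation).
#' @param effects Per-response effect tibble (see the default for its
#'   columns); effects act on centered log predictors.
#' @param templates Per-sex named vectors of mean canal measures.
#' @param landmark_noise_sd Per-coordinate observer jitter SD, mm.
#' @param fuzzy_noise_sd Jitter SD on the fuzzy ischial-tuberosity
#'   landmarks, mm (inflated relative to the rest).
#' @param observer_bias_sd SD of each observer's constant placement offset
#'   vector, mm.
#' @param n_observers,n_replicates Observers per specimen and replicates
#'   per observer (replicates re-digitise only the fuzzy landmarks).
#' @param pixel_spacing,slice_thickness Mask-stack raster geometry, mm
#'   (study slices are 5 mm thick).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_male = 44, n_female = 48, seed = 1,
                             weight_mean_male = 80.43, weight_sd_male = 19.27,
                             weight_mean_female = 67.17, weight_sd_female = 13.15,
                             stature_mean_male = 1.77, stature_sd_male = 0.07,
                             stature_mean_female = 1.64, stature_sd_female = 0.07,
                             gv_mean_female = 4192.13, gv_sd_female = 912.44,
                             gv_mean_male = 5384, allometry_b = 0.8,
                             gv_log_sd_male = 0.15,
                             effects = .default_effects(),
                             templates = .default_templates(),
                             landmark_noise_sd = 1, fuzzy_noise_sd = 5,
                             observer_bias_sd = 0.5,
                             n_observers = 2, n_replicates = 2,
                             pixel_spacing = c(1, 1), slice_thickness = 5) {
  cfg <- as.list(environment())
  sds <- c(weight_sd_male, weight_sd_female, gv_sd_female, gv_log_sd_male,
           landmark_noise_sd, fuzzy_noise_sd, observer_bias_sd)
  if (any(sds < 0)) abort_pelvi("All SDs must be >= 0.", "config_error")
  if (any(c(weight_mean_male, weight_mean_female, gv_mean_female, gv_mean_male) <= 0)) {
    abort_pelvi("Means of positive quantities must be > 0.", "config_error")
  }
  if (allometry_b <= 0 || allometry_b >= 1) {
    abort_pelvi("allometry_b must lie in (0, 1) for negative allometry.", "config_error")
  }
  if (n_male < 4 || n_female < 4) {
    abort_pelvi("At least 4 specimens per sex are required.", "config_error")
  }
  class(cfg) <- "generator_config"
  cfg
}

# delta-method moments of log X for X ~ Normal(mu, sd) truncated > 0
.log_moments <- function(mu, sd) {
  list(mean = log(mu) - sd^2 / (2 * mu^2), var = sd^2 / mu^2)
}

# male allometric intercept solved so that E[GV] matches the target mean
.allometry_intercept <- function(cfg) {
  lw <- .log_moments(cfg$weight_mean_male, cfg$weight_sd_male)
  tot_var <- cfg$allometry_b^2 * lw$var + cfg$gv_log_sd_male^2
  log(cfg$gv_mean_male) - cfg$allometry_b * lw$mean - tot_var / 2
}

.rnorm_pos <- function(n, mean, sd) {
  if (mean <= 0) abort_pelvi("Truncated normal needs a positive mean.", "config_error")
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a cohort
#'
#' Draws a synthetic cohort with the generator's statistical structure:
#' per-sex body weights and statures from truncated normals; female gut
#' volume normal and independent of weight; male gut volume log-normally
#' allometric on weight; and every canal measure generated in log space as
#' its sex template plus the configured effects of centered log GV and log
#' weight (plus the male interaction) plus normal residual. Shape indices
#' are derived as AP/ML of the generated dimensions.
#'
#' @param cfg A [generator_config()].
#' @return A cohort tibble: `specimen_id`, `sex`, `body_weight_kg`,
#'   `stature_m`, `gut_volume_cc` and the eleven canal responses, on the
#'   raw (unlogged) scale.
#' @export
simulate_cohort <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  a <- .allometry_intercept(cfg)

  one_sex <- function(sex, n) {
    if (sex == "male") {
      w <- .rnorm_pos(n, cfg$weight_mean_male, cfg$weight_sd_male)
      st <- .rnorm_pos(n, cfg$stature_mean_male, cfg$stature_sd_male)
      gv <- exp(a + cfg$allometry_b * log(w) +
                  stats::rnorm(n, 0, cfg$gv_log_sd_male))
      lw_mu <- .log_moments(cfg$weight_mean_male, cfg$weight_sd_male)$mean
      lgv_mu <- log(cfg$gv_mean_male) -
        (cfg$allometry_b^2 * .log_moments(cfg$weight_mean_male, cfg$weight_sd_male)$var +
           cfg$gv_log_sd_male^2) / 2
      bgv <- cfg$effects$beta_gv_male
      bw <- cfg$effects$beta_weight_male
      bint <- cfg$effects$beta_interaction_male
    } else {
      w <- .rnorm_pos(n, cfg$weight_mean_female, cfg$weight_sd_female)
      st <- .rnorm_pos(n, cfg$stature_mean_female, cfg$stature_sd_female)
      gv <- .rnorm_pos(n, cfg$gv_mean_female, cfg$gv_sd_female)
      lw_mu <- .log_moments(cfg$weight_mean_female, cfg$weight_sd_female)$mean
      lgv_mu <- .log_moments(cfg$gv_mean_female, cfg$gv_sd_female)$mean
      bgv <- cfg$effects$beta_gv_female
      bw <- cfg$effects$beta_weight_female
      bint <- rep(0, nrow(cfg$effects))
    }
    cgv <- log(gv) - lgv_mu
    cw <- log(w) - lw_mu
    template <- cfg$templates[[sex]][cfg$effects$response]
    base <- vapply(seq_len(nrow(cfg$effects)), function(i) {
      exp(log(template[i]) + bgv[i] * cgv + bw[i] * cw + bint[i] * cgv * cw +
            stats::rnorm(n, 0, cfg$effects$resid_sd[i]))
    }, numeric(n))
    if (is.null(dim(base))) base <- matrix(base, nrow = 1)
    colnames(base) <- cfg$effects$response
    tibble(
      specimen_id = sprintf("%s%03d", toupper(substr(sex, 1, 1)), seq_len(n)),
      sex = sex, body_weight_kg = w, stature_m = st, gut_volume_cc = gv
    ) %>% dplyr::bind_cols(as_tibble(base))
  }

  bind_rows(one_sex("male", cfg$n_male), one_sex("female", cfg$n_female)) %>%
    mutate(
      inlet_shape = shape_index(IAP, IML),
      midplane_shape = shape_index(MAP, MML),
      outlet_shape = shape_index(OAP, OML)
    ) %>%
    select(specimen_id, sex, body_weight_kg, stature_m, gut_volume_cc,
           dplyr::all_of(canal_responses()))
}

# Landmark template reproducing a row's six linear dimensions and both
# angles exactly. The spine/S5 triangle is fixed by MML, theta_a (at the S5
# apex) and theta_b (at the left spine) through the law of sines; the
# remaining landmarks are placed so each Table-3 pair realises its distance.
.landmark_template <- function(m) {
  rad <- function(d) d * pi / 180
  if (m[["theta_a"]] + m[["theta_b"]] >= 180) {
    abort_pelvi("theta_a + theta_b >= 180 degrees: spine/S5 triangle infeasible.",
                "infeasible_geometry_error")
  }
  th_c <- 180 - m[["theta_a"]] - m[["theta_b"]]          # angle at right spine
  d_l <- m[["MML"]] * sin(rad(th_c)) / sin(rad(m[["theta_a"]]))  # S5 to left spine
  spine_l <- c(-m[["MML"]] / 2, 0, 0)
  spine_r <- c(m[["MML"]] / 2, 0, 0)
  s5 <- spine_l + d_l * c(cos(rad(m[["theta_b"]])), -sin(rad(m[["theta_b"]])), 0)
  dips <- s5 + c(0, m[["OAP"]], 0)                      # dorsal inf. symphysis
  s4s5 <- dips + m[["MAP"]] * c(0, -cos(rad(35)), sin(rad(35)))
  dsps <- dips + c(0, 5, 45)                            # dorsal sup. symphysis
  prom <- dsps + m[["IAP"]] * c(0, -cos(rad(30)), sin(rad(30)))
  coords <- rbind(
    ischial_spine_L = spine_l,
    ischial_spine_R = spine_r,
    ischial_tuberosity_L = c(-m[["OML"]] / 2, 10, -20),
    ischial_tuberosity_R = c(m[["OML"]] / 2, 10, -20),
    sacral_promontory = prom,
    between_S4_S5 = s4s5,
    apex_S5 = s5,
    dorsal_sup_pubic_symphysis = dsps,
    dorsal_inf_pubic_symphysis = dips,
    max_iliopectineal_L = c(-m[["IML"]] / 2, 20, 40),
    max_iliopectineal_R = c(m[["IML"]] / 2, 20, 40)
  )
  colnames(coords) <- c("x_mm", "y_mm", "z_mm")
  coords
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate landmark digitisations for a cohort
#'
#' For each specimen, builds a landmark configuration whose canal
#' measurements reproduce the cohort row exactly, applies a random rigid
#' motion (each specimen sits in its own scanner frame), then adds
#' per-observer placement noise: a constant observer offset vector,
#' per-landmark Gaussian jitter, and inflated jitter on the fuzzy
#' ischial-tuberosity landmarks. Replicates within an observer re-digitise
#' only the fuzzy landmarks, emulating repeat measurement of the outlet ML
#' diameter.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param cfg The [generator_config()] used (noise and observer settings).
#' @param rigid Apply a random rigid motion per specimen (default TRUE).
#' @return A long landmark tibble (one row per landmark per specimen,
#'   observer and replicate).
#' @export
simulate_landmarks <- function(cohort, cfg = generator_config(), rigid = TRUE) {
  set.seed(cfg$seed + 1L)
  fuzzy_lms <- c("ischial_tuberosity_L", "ischial_tuberosity_R")
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    base <- .landmark_template(unlist(row[, c("IAP", "IML", "MAP", "MML",
                                              "OAP", "OML", "theta_a", "theta_b")]))
    if (rigid) {
      rot <- .random_rotation()
      shift <- stats::runif(3, -100, 100)
      base <- sweep(base %*% t(rot), 2, -shift)
    }
    purrr::map(seq_len(cfg$n_observers), function(obs) {
      bias <- stats::rnorm(3, 0, cfg$observer_bias_sd)
      jitter_base <- matrix(stats::rnorm(length(base), 0, cfg$landmark_noise_sd),
                            nrow(base), 3)
      purrr::map(seq_len(cfg$n_replicates), function(rep_i) {
        jitter <- jitter_base
        fz <- rownames(base) %in% fuzzy_lms
        jitter[fz, ] <- matrix(stats::rnorm(sum(fz) * 3, 0, cfg$fuzzy_noise_sd),
                               sum(fz), 3)
        pts <- sweep(base + jitter, 2, -bias)
        tibble(
          specimen_id = row$specimen_id,
          observer_id = sprintf("obs%d", obs),
          replicate_id = rep_i,
          landmark = rownames(base),
          x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3]
        )
      }) %>% list_rbind()
    }) %>% list_rbind()
  }) %>% list_rbind()
  validate_landmarks(rows)
}

#' Simulate a mask stack with a target gut volume
#'
#' Builds a multi-slice binary blob whose slice-summation volume matches
#' the target to within half a voxel (well inside 1% at the default 1 mm
#' spacing and 5 mm slices for realistic gut volumes). Positive pixels are
#' packed into square slices so the stack is exact by construction.
#'
#' @param gv_target Target volume, cc (> 0).
#' @param cfg A [generator_config()] (raster geometry).
#' @param specimen_id Identifier for the stack.
#' @param max_side Maximum slice side length, pixels.
#' @return A [mask_stack()].
#' @export
simulate_mask_stack <- function(gv_target, cfg = generator_config(),
                                specimen_id = "sim", max_side = 256) {
  if (gv_target <= 0) abort_pelvi("Target volume must be > 0.", "config_error")
  vox_mm3 <- cfg$pixel_spacing[1] * cfg$pixel_spacing[2] * cfg$slice_thickness
  n_pix <- round(gv_target * 1000 / vox_mm3)
  if (n_pix < 1) {
    abort_pelvi("Target volume is smaller than one voxel at this raster.",
                "resolution_error")
  }
  side <- min(max_side, ceiling(sqrt(n_pix)))
  per_slice <- side^2
  n_slice <- ceiling(n_pix / per_slice)
  slices <- lapply(seq_len(n_slice), function(k) {
    fill <- min(per_slice, n_pix - (k - 1) * per_slice)
    m <- matrix(FALSE, side, side)
    if (fill > 0) m[seq_len(fill)] <- TRUE
    m
  })
  mask_stack(slices, pixel_spacing = cfg$pixel_spacing,
             slice_thickness = cfg$slice_thickness, specimen_id = specimen_id)
}
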