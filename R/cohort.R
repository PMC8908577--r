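# Synthetic cohort generation: subjects with one or two eyes, ocular
# covariates drawn from configurable group-wise distributions, a smooth
# double-hump axonal cpRNFL profile with a temporally localized disease
# deficit, a vessel-density contribution to the measured profile, and
# ETDRS macular layer grids.

GROUPS <- c("control", "mci", "ad")

default_covariate_params <- function() {
  g3 <- function(m, s) list(mean = stats::setNames(m, GROUPS),
                            sd   = stats::setNames(s, GROUPS))
  list(
    age               = g3(c(71.0, 73.4, 73.3), c(4.7, 6.3, 8.7)),
    refractive_error  = g3(c(-1.11, 0.03, -0.06), c(2.76, 1.88, 1.67)),
    disc_area         = g3(c(1.86, 1.97, 1.98), c(0.39, 0.39, 0.35)),
    disc_ratio        = g3(rep(1.13, 3), rep(0.09, 3)),
    disc_orientation  = g3(rep(95.85, 3), rep(33.15, 3)),
    fovea_distance    = g3(rep(4.52, 3), rep(0.29, 3)),
    fovea_angle       = g3(rep(-8.06, 3), rep(3.95, 3)),
    signal_strength   = g3(rep(7.56, 3), rep(1.05, 3)),
    diabetes_prev     = stats::setNames(c(0.15, 0.32, 0.34), GROUPS)
  )
}

default_macular_means <- function() {
  m <- rbind(
    mrnfl = c(10, 24, 21, 25, 17, 35, 45, 37, 19),
    mgcl  = c(14, 50, 48, 49, 46, 34, 36, 35, 33),
    mipl  = c(21, 40, 36, 39, 39, 29, 31, 30, 28)
  )
  colnames(m) <- ETDRS_SECTORS
  m
}

default_effect_params <- function() {
  list(
    # measured control profile calibration (micrometers, at reference age)
    temporal_mean = 74, superior_mean = 115,
    age_ref = 71, age_slope = -0.2,
    # disease deficit: temporal-quadrant mean thinning in micrometers
    cprnfl_deficit = stats::setNames(c(0, 5, 5), GROUPS),
    deficit_center_deg = 45, deficit_kappa = 3,
    # peripapillary vessel density (dimensionless density units)
    vd_quadrant_means = c(temporal = 2.05, superior = 4.5,
                          nasal = 3.2, inferior = 4.59),
    vd_group_effect = list(
      mci = list(quadrant = "temporal", amount = -0.26),
      ad  = list(quadrant = "inferior", amount = 0.48)
    ),
    vd_scale_sd = 0.12, vd_noise_sd = 0.4, vd_shape_sd = 0.6,
    # subject-level disease severity multiplier (SD of the lognormal-ish
    # scaling applied to all group deficits)
    severity_sd = 0.3,
    # generating coefficients of non-vascular covariate effects on
    # measured cpRNFL (micrometers per covariate unit)
    covariate_effects = c(disc_area = 10, refractive_error = 2,
                          signal_strength = 2.5, diabetes = -1),
    ethnicity_shift = c(chinese = 0, malay = -2, indian = 2),
    # macular layers: control means and uniform group deficits
    macular_means = default_macular_means(),
    macular_deficit = rbind(
      control = c(mrnfl = 0, mgcl = 0,   mipl = 0),
      mci     = c(mrnfl = 2, mgcl = 1.5, mipl = 2),
      ad      = c(mrnfl = 3, mgcl = 2.5, mipl = 3)
    ),
    macular_subject_sd = 3.5, macular_noise_sd = 2.5
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()].  Defaults are
#' calibrated to a memory-clinic OCT cohort: group-wise covariate
#' distributions, a ~5 micrometer temporal-quadrant cpRNFL deficit in
#' cognitively impaired groups, and a vessel-density coupling tuned so the
#' correlation between mean vessel density and mean measured cpRNFL across
#' eyes is about 0.2.
#'
#' @param n_control,n_mci,n_ad subject counts per group (all >= 1).
#' @param p_two_eyes probability that both eyes of a subject are usable.
#' @param within_subject_rho correlation between eye-level latent effects of
#'   the two eyes of one subject, in `[0, 1)`.
#' @param vessel_coupling micrometers of measured cpRNFL per unit vessel
#'   density; applied to the deviation of an eye's sector density from the
#'   population profile, so the population mean thickness is unaffected.
#' @param subject_sd standard deviation (micrometers) of the eye-level
#'   global thickness offset (shared between fellow eyes with correlation
#'   `within_subject_rho`).
#' @param shape_sd standard deviation (micrometers) of the eye-level
#'   low-order Fourier variation of the profile shape (individual anatomy
#'   of the nerve fiber bundles, not explained by the measured covariates).
#' @param noise_sd residual per-sector measurement noise SD (micrometers).
#' @param p_artifact probability an eye is flagged with a movement artifact.
#' @param ethnicity_probs named probabilities of the ethnicity categories.
#' @param covariate_params,effect_params optional partial overrides of the
#'   default distribution and effect parameters (merged recursively).
#' @param seed integer RNG seed; generation is deterministic given the
#'   configuration.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_control = 55, n_mci = 108, n_ad = 62,
                          p_two_eyes = 0.5,
                          within_subject_rho = 0.6,
                          vessel_coupling = 4.2,
                          subject_sd = 6, shape_sd = 7, noise_sd = 3.5,
                          p_artifact = 0.02,
                          ethnicity_probs = c(chinese = 0.7, malay = 0.2,
                                              indian = 0.1),
                          covariate_params = list(),
                          effect_params = list(),
                          seed = 1L) {
  for (nm in c("n_control", "n_mci", "n_ad")) {
    n <- get(nm)
    if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
      stop("'", nm, "' must be a positive integer count", call. = FALSE)
  }
  stopifnot_scalar(p_two_eyes, "p_two_eyes", 0, 1)
  if (!is.numeric(within_subject_rho) || within_subject_rho < 0 ||
      within_subject_rho >= 1)
    stop("'within_subject_rho' must lie in [0, 1)", call. = FALSE)
  stopifnot_scalar(vessel_coupling, "vessel_coupling", 0)
  stopifnot_scalar(subject_sd, "subject_sd", 0)
  stopifnot_scalar(shape_sd, "shape_sd", 0)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  stopifnot_scalar(p_artifact, "p_artifact", 0, 1)
  if (abs(sum(ethnicity_probs) - 1) > 1e-8 || any(ethnicity_probs < 0))
    stop("'ethnicity_probs' must be non-negative and sum to 1", call. = FALSE)

  cp <- utils::modifyList(default_covariate_params(), covariate_params)
  ep <- utils::modifyList(default_effect_params(), effect_params)
  for (v in setdiff(names(cp), "diabetes_prev"))
    if (any(cp[[v]]$sd <= 0))
      stop("covariate SDs must be positive (", v, ")", call. = FALSE)

  structure(list(
    n_control = as.integer(n_control), n_mci = as.integer(n_mci),
    n_ad = as.integer(n_ad),
    p_two_eyes = p_two_eyes, within_subject_rho = within_subject_rho,
    vessel_coupling = vessel_coupling, subject_sd = subject_sd,
    shape_sd = shape_sd, noise_sd = noise_sd, p_artifact = p_artifact,
    ethnicity_probs = ethnicity_probs,
    covariate_params = cp, effect_params = ep,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# von Mises-style circular bump, peak 1 at mu (radians)
vm_bump <- function(theta, mu, kappa) exp(kappa * (cos(theta - mu) - 1))

# Base double-hump shape (superior/inferior peaks) on the 256 sector centers
tsnit_shape <- function() {
  th <- sector_center_angles()
  vm_bump(th, 3 * pi / 4, 4) + vm_bump(th, 7 * pi / 4, 4)
}

# Deficit shape normalized so its temporal-quadrant mean is exactly 1.
deficit_shape <- function(effect) {
  th <- sector_center_angles()
  b <- vm_bump(th, effect$deficit_center_deg * pi / 180, effect$deficit_kappa)
  b / mean(b[QUADRANTS$temporal])
}

#' Axonal cpRNFL template profile
#'
#' Smooth 256-sector profile with superior and inferior peaks, a linear age
#' slope, and a temporally localized group deficit whose temporal-quadrant
#' mean equals exactly the configured thinning.
#'
#' @param age age in years (> 0).
#' @param group one of `"control"`, `"mci"`, `"ad"`.
#' @param effect_params effect parameter list as in [cohort_config()].
#' @return numeric vector of 256 sector thicknesses (micrometers).
#' @export
axonal_template <- function(age, group = "control",
                            effect_params = default_effect_params()) {
  stopifnot(age > 0)
  group <- match.arg(group, GROUPS)
  ep <- effect_params
  shape <- tsnit_shape()
  mT <- mean(shape[QUADRANTS$temporal])
  mS <- mean(shape[QUADRANTS$superior])
  A  <- (ep$superior_mean - ep$temporal_mean) / (mS - mT)
  c0 <- ep$temporal_mean - A * mT
  base <- c0 + A * shape + ep$age_slope * (age - ep$age_ref)
  base - ep$cprnfl_deficit[[group]] * deficit_shape(ep)
}

# Smooth vessel-density population profile matching the four configured
# quadrant means, via a low-order Fourier expansion.
vd_base_profile <- function(qmeans) {
  th <- sector_center_angles()
  basis <- cbind(1, cos(th), sin(th), sin(2 * th))
  M <- t(vapply(QUADRANTS, function(ix) colMeans(basis[ix, ]), numeric(4)))
  b <- solve(M, as.numeric(qmeans[names(QUADRANTS)]))
  pmax(as.numeric(basis %*% b), 0.05)
}

# Eye-level smooth profile shape variation: random low-order Fourier
# series (k = 1, 2) with pointwise SD `sd`, correlated within subjects.
fourier_wiggle <- function(subj_ix, n_subjects, rho, sd) {
  th <- sector_center_angles()
  F <- cbind(cos(th), sin(th), cos(2 * th), sin(2 * th))
  coefs <- vapply(1:4, function(k) rho_normal(subj_ix, n_subjects, rho),
                  numeric(length(subj_ix)))
  (sd / sqrt(2)) * coefs %*% t(F)
}

vd_group_bump <- function(eff) {
  centers <- c(temporal = 45, superior = 135, nasal = 225, inferior = 315)
  th <- sector_center_angles()
  b <- vm_bump(th, centers[[eff$quadrant]] * pi / 180, 3)
  eff$amount * b / mean(b[QUADRANTS[[eff$quadrant]]])
}

#' Generate a synthetic cohort of eyes
#'
#' Draws subjects in three groups with configured covariate distributions;
#' each subject contributes one or two eyes whose eye-level latent effects
#' (anatomy, global thickness offset) are correlated with
#' `within_subject_rho`.  The measured cpRNFL profile of an eye is the
#' axonal template plus the vessel-density deviation scaled by the coupling
#' coefficient, plus centered covariate effects, a global offset, and
#' per-sector noise.  The noiseless axonal profile is retained in
#' `truth_*` columns.
#'
#' @param config a [cohort_config()] object.
#' @return a `data.frame` with one row per eye: identifiers, covariates,
#'   `rnfl_000..rnfl_255` measured thickness, `vd_000..vd_255` vessel
#'   density, macular layer columns `<layer>_<etdrs sector>`, and
#'   `truth_000..truth_255` axonal profiles.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be created by cohort_config()", call. = FALSE)
  set.seed(config$seed)
  cp <- config$covariate_params
  ep <- config$effect_params
  rho <- config$within_subject_rho

  n_subj <- config$n_control + config$n_mci + config$n_ad
  grp_subj <- factor(rep(GROUPS, c(config$n_control, config$n_mci, config$n_ad)),
                     levels = GROUPS)

  # subject-level draws
  age_subj <- stats::rnorm(n_subj, cp$age$mean[grp_subj], cp$age$sd[grp_subj])
  age_subj <- pmax(50, age_subj)
  eth_subj <- factor(sample(names(config$ethnicity_probs), n_subj,
                            replace = TRUE, prob = config$ethnicity_probs),
                     levels = names(config$ethnicity_probs))
  diab_subj <- stats::rbinom(n_subj, 1, cp$diabetes_prev[grp_subj]) == 1
  two_eyes <- stats::rbinom(n_subj, 1, config$p_two_eyes) == 1

  subj_ix <- rep(seq_len(n_subj), ifelse(two_eyes, 2L, 1L))
  n_eye <- length(subj_ix)
  eye <- unlist(lapply(seq_len(n_subj), function(i) {
    if (two_eyes[i]) c("right", "left") else sample(c("right", "left"), 1)
  }), use.names = FALSE)

  grp <- grp_subj[subj_ix]
  gi <- as.integer(grp)

  draw_eye_cov <- function(name) {
    p <- cp[[name]]
    p$mean[gi] + p$sd[gi] * rho_normal(subj_ix, n_subj, rho)
  }
  refr  <- draw_eye_cov("refractive_error")
  darea <- pmax(0.5, draw_eye_cov("disc_area"))
  drat  <- pmax(1, draw_eye_cov("disc_ratio"))
  dori  <- draw_eye_cov("disc_orientation") %% 180
  fdist <- pmax(2, draw_eye_cov("fovea_distance"))
  fang  <- draw_eye_cov("fovea_angle")
  # scan quality is independent between fellow eyes
  sigs  <- pmin(10, pmax(0, stats::rnorm(
    n_eye, cp$signal_strength$mean[gi], cp$signal_strength$sd[gi])))

  # subject-level disease severity scaling of all group deficits
  severity <- pmax(0, 1 + ep$severity_sd * stats::rnorm(n_subj))[subj_ix]

  # vessel density profiles (rows = eyes)
  vd_ctrl <- vd_base_profile(ep$vd_quadrant_means)
  vd_bump <- rbind(control = rep(0, N_SECTORS),
                   mci = vd_group_bump(ep$vd_group_effect$mci),
                   ad  = vd_group_bump(ep$vd_group_effect$ad))
  scale_eye <- 1 + ep$vd_scale_sd * rho_normal(subj_ix, n_subj, rho)
  vd <- matrix(vd_ctrl, n_eye, N_SECTORS, byrow = TRUE) * scale_eye +
    vd_bump[gi, , drop = FALSE] * severity +
    fourier_wiggle(subj_ix, n_subj, rho, ep$vd_shape_sd) +
    matrix(stats::rnorm(n_eye * N_SECTORS, 0, ep$vd_noise_sd), n_eye)
  vd <- pmax(vd, 0.05)

  # axonal truth: control base + age slope + individual shape - group deficit
  shape <- tsnit_shape()
  mT <- mean(shape[QUADRANTS$temporal]); mS <- mean(shape[QUADRANTS$superior])
  A  <- (ep$superior_mean - ep$temporal_mean) / (mS - mT)
  c0 <- ep$temporal_mean - A * mT
  offset <- config$subject_sd * rho_normal(subj_ix, n_subj, rho)
  axonal <- matrix(c0 + A * shape, n_eye, N_SECTORS, byrow = TRUE) +
    ep$age_slope * (age_subj[subj_ix] - ep$age_ref) +
    offset + fourier_wiggle(subj_ix, n_subj, rho, config$shape_sd) -
    outer(ep$cprnfl_deficit[gi] * severity, deficit_shape(ep))

  # centered covariate effects (zero in expectation for controls)
  ce <- ep$covariate_effects
  eth_shift <- ep$ethnicity_shift[as.character(eth_subj[subj_ix])]
  eth_shift <- eth_shift - sum(config$ethnicity_probs *
                                 ep$ethnicity_shift[names(config$ethnicity_probs)])
  cov_eff <-
    ce[["disc_area"]] * (darea - cp$disc_area$mean[["control"]]) +
    ce[["refractive_error"]] * (refr - cp$refractive_error$mean[["control"]]) +
    ce[["signal_strength"]] * (sigs - cp$signal_strength$mean[["control"]]) +
    ce[["diabetes"]] * (diab_subj[subj_ix] - cp$diabetes_prev[["control"]]) +
    eth_shift

  vd_dev <- vd - matrix(vd_ctrl, n_eye, N_SECTORS, byrow = TRUE)
  measured <- axonal + config$vessel_coupling * vd_dev + cov_eff +
    matrix(stats::rnorm(n_eye * N_SECTORS, 0, config$noise_sd), n_eye)
  measured <- pmax(measured, 1)

  # macular layers: per-layer latent subject effect + sector noise
  mac <- matrix(NA_real_, n_eye, length(MACULAR_LAYERS) * 9)
  colnames(mac) <- macular_cols()
  for (layer in MACULAR_LAYERS) {
    base <- ep$macular_means[layer, ]
    def <- ep$macular_deficit[gi, layer] * severity
    lat <- ep$macular_subject_sd * rho_normal(subj_ix, n_subj, rho)
    vals <- matrix(base, n_eye, 9, byrow = TRUE) - def + lat +
      matrix(stats::rnorm(n_eye * 9, 0, ep$macular_noise_sd), n_eye)
    mac[, paste(layer, ETDRS_SECTORS, sep = "_")] <- pmax(vals, 1)
  }

  out <- data.frame(
    subject_id = sprintf("S%04d", subj_ix),
    eye = eye,
    group = as.character(grp),
    age = age_subj[subj_ix],
    ethnicity = as.character(eth_subj[subj_ix]),
    diabetes = diab_subj[subj_ix],
    refractive_error = refr,
    signal_strength = sigs,
    disc_area = darea,
    disc_ratio = drat,
    disc_orientation = dori,
    fovea_distance = fdist,
    fovea_angle = fang,
    artifact = stats::rbinom(n_eye, 1, config$p_artifact) == 1,
    stringsAsFactors = FALSE
  )
  m <- measured; colnames(m) <- sector_cols("rnfl")
  v <- vd;       colnames(v) <- sector_cols("vd")
  tr <- axonal;  colnames(tr) <- sector_cols("truth")
  out <- cbind(out, as.data.frame(m), as.data.frame(v),
               as.data.frame(mac), as.data.frame(tr))
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Write / read a cohort as CSV
#'
#' One row per eye; sector profiles as suffixed columns
#' (`rnfl_000..rnfl_255`, `vd_000..vd_255`), macular grid as
#' `<layer>_<sector>` columns.
#'
#' @param cohort data.frame from [generate_cohort()] or of the same schema.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "group", "age", "signal_strength",
            sector_cols("rnfl"), sector_cols("vd"))
  missing <- setdiff(need, names(x))
  if (length(missing) > 0)
    stop("cohort file is missing required columns, e.g. ", missing[1])
  x
}
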