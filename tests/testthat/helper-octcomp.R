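# shared fixtures and independent oracles

# O(n^2) pair-counting AUC oracle (ties count one half)
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  cases <- scores[labels]; ctrls <- scores[!labels]
  tot <- 0
  for (x in cases) for (y in ctrls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(ctrls))
}

# per-pixel double-loop oracle for annular sector density
sector_density_bruteforce <- function(mask, disc_center, pixel_scale,
                                      radii = c(1.64, 1.82)) {
  tot <- ves <- numeric(256)
  for (row in seq_len(nrow(mask))) {
    for (col in seq_len(ncol(mask))) {
      x <- (col - 0.5) * pixel_scale - disc_center[1]
      y <- (row - 0.5) * pixel_scale - disc_center[2]
      r <- sqrt(x^2 + y^2)
      if (r >= radii[1] && r < radii[2]) {
        th <- atan2(-y, x) %% (2 * pi)
        s <- min(256, floor(th / (2 * pi / 256)) + 1)
        tot[s] <- tot[s] + 1
        if (mask[row, col]) ves[s] <- ves[s] + 1
      }
    }
  }
  ifelse(tot > 0, ves / tot, NA_real_)
}

# a small quiet cohort: no covariate effects, optional confound
quiet_config <- function(seed, n_control = 55, n_mci = 1, n_ad = 1,
                         vessel_coupling = 0, noise_sd = 0, subject_sd = 0,
                         shape_sd = 0, ...) {
  cohort_config(
    n_control = n_control, n_mci = n_mci, n_ad = n_ad,
    vessel_coupling = vessel_coupling, noise_sd = noise_sd,
    subject_sd = subject_sd, shape_sd = shape_sd, p_artifact = 0,
    effect_params = list(
      covariate_effects = c(disc_area = 0, refractive_error = 0,
                            signal_strength = 0, diabetes = 0),
      ethnicity_shift = c(chinese = 0, malay = 0, indian = 0),
      cprnfl_deficit = stats::setNames(c(0, 0, 0), c("control", "mci", "ad")),
      severity_sd = 0),
    seed = seed, ...)
}

rnfl_mat <- function(cohort) as.matrix(cohort[, sprintf("rnfl_%03d", 0:255)])
vd_mat <- function(cohort) as.matrix(cohort[, sprintf("vd_%03d", 0:255)])
truth_mat <- function(cohort) as.matrix(cohort[, sprintf("truth_%03d", 0:255)])
temporal_mean <- function(m) rowMeans(m[, 1:64, drop = FALSE])
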