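test_that("Gaussian AIC has its closed-form identities", {
  expect_equal(aic_gaussian(rss = 50, n = 50, k = 1), 4)   # ln(1) = 0
  n <- 37
  a1 <- aic_gaussian(10, n, 3)
  a2 <- aic_gaussian(20, n, 3)
  expect_equal(a2 - a1, n * log(2))
  a0 <- aic_gaussian(0, n, 2)
  expect_identical(unclass(a0)[1], -Inf)
  expect_true(attr(a0, "exact_fit"))
  expect_error(aic_gaussian(10, 3, 5))
})

test_that("AIC ranking agrees with the explicit Gaussian likelihood", {
  set.seed(8)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n); y <- 1 + 2 * x1 + rnorm(n)
  fits <- list(lm(y ~ 1), lm(y ~ x1), lm(y ~ x2), lm(y ~ x1 + x2))
  ours <- vapply(fits, function(f)
    aic_gaussian(sum(resid(f)^2), n, length(coef(f))), numeric(1))
  ref <- vapply(fits, stats::AIC, numeric(1))
  # identical up to the additive constant n * (log(2*pi) + 1)
  expect_equal(ours + n * (log(2 * pi) + 1), ref, tolerance = 1e-10)
  expect_equal(order(ours), order(ref))
})

test_that("noiseless generation is identified to machine precision", {
  cc <- quiet_config(seed = 12, n_control = 60, vessel_coupling = 5)
  coh <- generate_cohort(cc)
  m <- fit_compensation(coh, candidates = c("age", "vessel_density"))
  # age slope and vessel coupling are the only generating effects
  expect_true(all(m$selected[, "vessel_density"]))
  expect_equal(unname(m$coefficients[, "vessel_density"]), rep(5, 256),
               tolerance = 1e-6)
  expect_equal(unname(m$coefficients[, "age"]), rep(-0.2, 256),
               tolerance = 1e-6)
})

test_that("vessel coupling is recovered from noisy confounded cohorts", {
  sel_frac <- beta_hat <- numeric(3)
  for (i in 1:3) {
    cc <- quiet_config(seed = 100 + i, n_control = 300, vessel_coupling = 5,
                       noise_sd = 3.5, subject_sd = 6, shape_sd = 7)
    coh <- generate_cohort(cc)
    m <- fit_compensation(coh)
    sel_frac[i] <- mean(m$selected[, "vessel_density"])
    beta_hat[i] <- mean(m$coefficients[m$selected[, "vessel_density"],
                                       "vessel_density"])
  }
  expect_true(all(sel_frac >= 0.8))
  expect_lt(abs(mean(beta_hat) - 5) / 5, 0.1)
})

test_that("pure-noise thickness selects near-empty models", {
  sizes <- numeric(3)
  for (i in 1:3) {
    cc <- quiet_config(seed = 200 + i, n_control = 300, noise_sd = 6)
    coh <- generate_cohort(cc)
    m <- fit_compensation(coh)
    sizes[i] <- stats::median(rowSums(m$selected))
  }
  expect_true(all(sizes <= 2))
})

test_that("compensation is the identity at the training means", {
  coh <- generate_cohort(cohort_config(n_control = 40, n_mci = 1, n_ad = 1,
                                       seed = 33))
  m <- fit_compensation(coh, selection = "forward")
  ctrl <- coh[coh$group == "control", ]
  probe <- ctrl[1, ]
  for (v in c("age", "refractive_error", "signal_strength", "disc_area",
              "disc_ratio", "disc_orientation", "fovea_distance",
              "fovea_angle"))
    probe[[v]] <- mean(ctrl[[v]])
  probe[, sprintf("vd_%03d", 0:255)] <- colMeans(vd_mat(ctrl))
  probe$ethnicity <- "chinese"
  m2 <- fit_compensation(ctrl, candidates = setdiff(octcomp:::COMP_CANDIDATES,
                                                    "ethnicity"),
                         selection = "forward")
  comp <- predict(m2, probe)
  expect_equal(as.numeric(comp), as.numeric(probe[, sprintf("rnfl_%03d", 0:255)]),
               tolerance = 1e-8)
})

test_that("a known coefficient subtracts linearly", {
  coh <- generate_cohort(quiet_config(seed = 44, n_control = 40,
                                      vessel_coupling = 5))
  m <- fit_compensation(coh, candidates = c("age", "vessel_density"))
  eye <- coh[1, ]
  base <- predict(m, eye)
  eye2 <- eye
  eye2$vd_010 <- eye$vd_010 + 1         # one density unit above
  shifted <- predict(m, eye2)
  expect_equal(shifted[1, 11] - base[1, 11], -5, tolerance = 1e-6)
  expect_equal(shifted[1, -11], base[1, -11], ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("compensation is affine-equivariant and mean-preserving", {
  coh <- generate_cohort(cohort_config(n_control = 50, n_mci = 1, n_ad = 1,
                                       seed = 55))
  ctrl <- coh[coh$group == "control", ]
  m <- fit_compensation(ctrl, selection = "forward", train_group = NULL)
  comp <- predict(m, ctrl)
  # training-mean preservation per sector
  expect_equal(colMeans(comp), colMeans(rnfl_mat(ctrl)), tolerance = 1e-8,
               ignore_attr = TRUE)
  shifted <- ctrl
  shifted[, sprintf("rnfl_%03d", 0:255)] <-
    ctrl[, sprintf("rnfl_%03d", 0:255)] + 10
  expect_equal(predict(m, shifted), comp + 10, ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("an empty candidate set makes compensation the identity", {
  coh <- generate_cohort(cohort_config(n_control = 30, n_mci = 1, n_ad = 1,
                                       seed = 66))
  m <- fit_compensation(coh, candidates = character(0))
  expect_equal(predict(m, coh), rnfl_mat(coh), ignore_attr = TRUE)
})

test_that("AIC selection does not overfit out of sample", {
  # compare held-out regression RSS of the AIC model vs the full model
  cands <- c("age", "disc_area", "refractive_error", "fovea_angle",
             "vessel_density")
  delta <- numeric(10)
  for (i in seq_along(delta)) {
    cc <- quiet_config(seed = 300 + i, n_control = 67, vessel_coupling = 3,
                       noise_sd = 4, subject_sd = 5, shape_sd = 5)
    train <- generate_cohort(cc)
    cc2 <- cc; cc2$seed <- 900 + i
    test <- generate_cohort(cc2)
    maic <- fit_compensation(train, candidates = cands)
    pred_rss <- function(model, dat) {
      comp <- predict(model, dat)
      fit <- rnfl_mat(dat) - comp +
        matrix(model$intercept +
                 rowSums(model$coefficients * model$xbar),
               nrow(dat), 256, byrow = TRUE)
      sum((rnfl_mat(dat) - fit)^2)
    }
    # full model: every candidate forced in, via per-sector OLS oracle
    Zf <- cbind(age = train$age, disc_area = train$disc_area,
                refractive_error = train$refractive_error,
                fovea_angle = train$fovea_angle)
    Zt <- cbind(age = test$age, disc_area = test$disc_area,
                refractive_error = test$refractive_error,
                fovea_angle = test$fovea_angle)
    Vf <- vd_mat(train); Vt <- vd_mat(test)
    rss_full <- 0
    for (s in 1:256) {
      f <- stats::lm.fit(cbind(1, Zf, Vf[, s]), rnfl_mat(train)[, s])
      pr <- cbind(1, Zt, Vt[, s]) %*% f$coefficients
      rss_full <- rss_full + sum((rnfl_mat(test)[, s] - pr)^2)
    }
    delta[i] <- pred_rss(maic, test) - rss_full
  }
  expect_lte(mean(delta), 0)
})

test_that("constant covariates are dropped with a warning", {
  coh <- generate_cohort(cohort_config(n_control = 40, n_mci = 1, n_ad = 1,
                                       seed = 77))
  coh$signal_strength <- 8
  expect_warning(
    m <- fit_compensation(coh, candidates = c("age", "signal_strength",
                                              "vessel_density"),
                          selection = "forward"),
    "constant")
  expect_false("signal_strength" %in% m$candidates)
})

test_that("model JSON serialization round-trips predictions", {
  coh <- generate_cohort(cohort_config(n_control = 40, n_mci = 1, n_ad = 1,
                                       seed = 88))
  m <- fit_compensation(coh, selection = "forward")
  path <- withr::local_tempfile(fileext = ".json")
  write_compensation(m, path)
  m2 <- read_compensation(path)
  expect_equal(predict(m2, coh), predict(m, coh), tolerance = 1e-12)
  expect_equal(m2$aic, m$aic, tolerance = 1e-12)
})

test_that("decorrelation check matches the textbook Pearson formula", {
  coh <- generate_cohort(cohort_config(n_control = 40, n_mci = 1, n_ad = 1,
                                       seed = 99))
  m <- fit_compensation(coh, selection = "forward")
  dc <- decorrelation_check(coh, m)
  x <- rowMeans(vd_mat(coh)); y <- rowMeans(rnfl_mat(coh))
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(dc$r_measured, r_manual, tolerance = 1e-12)
  expect_error(decorrelation_check(coh[1:10, ], m), "at least 50")
})
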