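test_that("logistic fit matches an independent Newton solve", {
  # tiny fixed design: 8 observations, 2 overlapping features
  x <- cbind(a = c(0.2, 0.3, 0.5, 0.4, 0.8, 0.9, 0.7, 0.6),
             b = c(1.0, 0.2, 0.5, 0.3, 0.8, 0.9, 0.4, 0.6))
  y <- c(0, 1, 0, 0, 1, 0, 1, 1)
  f <- fit_logistic(x, y)
  # hand-rolled Newton iteration on the unpenalized likelihood
  X <- cbind(1, x)
  beta <- rep(0, 3)
  for (i in 1:50) {
    p <- stats::plogis(drop(X %*% beta))
    W <- diag(p * (1 - p))
    beta <- beta + solve(t(X) %*% W %*% X, t(X) %*% (y - p))
  }
  expect_equal(unname(f$coefficients), unname(drop(beta)), tolerance = 1e-6)
  g <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial))
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-5)
})

test_that("separable and null features give extreme and chance AUC", {
  set.seed(10)
  y <- rep(c(0, 1), each = 200)
  x_sep <- matrix(y + rnorm(400, sd = 0.01), ncol = 1)
  f <- suppressWarnings(fit_logistic(x_sep, y))
  expect_gt(roc_auc(f$scores, y), 0.99)
  x_null <- matrix(rnorm(400), ncol = 1)
  f0 <- fit_logistic(x_null, y)
  expect_lt(abs(roc_auc(f0$scores, y) - 0.5), 0.06)
  expect_error(fit_logistic(x_null, rep(1, 400)), "both classes")
})

test_that("AUC equals the pair-counting oracle, ties included", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(20)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_identical(roc_auc(scores, labels),
                     auc_bruteforce(scores, labels))
    # invariance under strictly increasing transforms
    expect_identical(roc_auc(scores, labels),
                     roc_auc(exp(3 * scores), labels))
  }
})

test_that("sensitivity at fixed specificity matches a threshold sweep", {
  y <- c(rep(0, 5), rep(1, 5))
  expect_equal(sensitivity_at_specificity(c(1:5, 11:15) / 20, y), 100)
  expect_equal(sensitivity_at_specificity(1 - y, y, 0.80), 0)
  set.seed(30)
  scores <- round(stats::runif(10), 2)
  # exhaustive sweep oracle
  oracle <- function(scores, labels, spec) {
    best <- 0
    for (t in c(sort(unique(scores)), Inf)) {
      if (mean(scores[labels == 0] < t) >= spec)
        best <- max(best, mean(scores[labels == 1] >= t))
    }
    100 * best
  }
  expect_equal(sensitivity_at_specificity(scores, y, 0.8),
               oracle(scores, y, 0.8))
  # non-increasing in the required specificity
  sens <- vapply(c(0.5, 0.7, 0.8, 0.9, 1),
                 function(sp) sensitivity_at_specificity(scores, y, sp),
                 numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("DeLong test is symmetric and degenerates to p = 1", {
  set.seed(40)
  y <- rep(c(0, 1), each = 20)
  a <- rnorm(40) + y
  b <- rnorm(40) + 0.5 * y
  d1 <- delong_test(a, b, y)
  d2 <- delong_test(b, a, y)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)
  ident <- delong_test(a, a, y)
  expect_equal(ident$p, 1)
  expect_true(ident$degenerate)
})

test_that("DeLong variance matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  y <- rep(c(0, 1), c(6, 6))
  a <- rnorm(12) + y
  b <- rnorm(12) + 0.8 * y
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(ours$z), abs(unname(ref$statistic)), tolerance = 1e-10)
})

test_that("clustered bootstrap of a constant is a point interval", {
  x <- rep(3.5, 20)
  subj <- rep(1:10, each = 2)
  bs <- clustered_bootstrap(function(idx) mean(x[idx]), subj, B = 100,
                            seed = 1)
  expect_equal(bs$ci, c(3.5, 3.5))
  expect_equal(bs$estimate, 3.5)
})

test_that("with singleton clusters the clustered bootstrap is the ordinary one", {
  set.seed(50)
  y <- rep(c(FALSE, TRUE), each = 40)
  scores <- rnorm(80) + 0.8 * y
  stat <- function(idx) {
    yy <- y[idx]
    if (!any(yy) || all(yy)) return(NA_real_)
    roc_auc(scores[idx], yy)
  }
  cl <- clustered_bootstrap(stat, subjects = seq_along(y), B = 600, seed = 7)
  # ordinary bootstrap with the same scheme: resample rows directly
  set.seed(7)
  reps <- numeric(600)
  for (b in 1:600) {
    repeat {
      idx <- sample.int(80, replace = TRUE)
      v <- stat(idx)
      if (is.finite(v)) break
    }
    reps[b] <- v
  }
  expect_lt(max(abs(quantile(cl$replicates, c(0.1, 0.5, 0.9)) -
                      quantile(reps, c(0.1, 0.5, 0.9)))), 0.05)
})

test_that("post-hoc power has its limiting identities", {
  expect_equal(posthoc_power(10, 2, 50, 10, 2, 50), 5, tolerance = 1e-8)
  # monotone in effect size and in n
  deltas <- seq(0, 3, by = 0.5)
  pw <- vapply(deltas, function(d) posthoc_power(10 + d, 4, 40, 10, 4, 40),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  ns <- c(10, 20, 50, 100, 500, 5000)
  pn <- vapply(ns, function(n) posthoc_power(12, 4, n, 10, 4, n), numeric(1))
  expect_true(all(diff(pn) > 0))
  expect_gt(pn[length(ns)], 99.9)
  expect_error(posthoc_power(1, 0, 10, 2, 1, 10))
})

test_that("comparison rows are consistent with their own score vectors", {
  coh <- generate_cohort(cohort_config(n_control = 40, n_mci = 30, n_ad = 20,
                                       seed = 61))
  m <- fit_compensation(coh, selection = "forward")
  tab <- suppressWarnings(
    build_comparison(coh, m, contrast = "cases_vs_control", B = 50, seed = 3))
  scores <- attr(tab, "scores"); labels <- attr(tab, "labels")
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$auc[i], roc_auc(scores[[i]], labels))
  expect_true(all(tab$ci_lower <= tab$auc & tab$auc <= tab$ci_upper))
  expect_true(all(tab$sens_at_spec >= 0 & tab$sens_at_spec <= 100))
  expect_true(is.na(tab$delong_p[1]))
  # determinism given the seed
  tab2 <- suppressWarnings(
    build_comparison(coh, m, contrast = "cases_vs_control", B = 50, seed = 3))
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("a null cohort yields chance-level discrimination", {
  cc <- quiet_config(seed = 71, n_control = 60, n_mci = 60, n_ad = 60,
                     noise_sd = 3.5, subject_sd = 6, shape_sd = 7,
                     vessel_coupling = 4.2)
  coh <- generate_cohort(cc)
  m <- fit_compensation(coh, selection = "forward")
  tab <- suppressWarnings(
    build_comparison(coh, m, contrast = "cases_vs_control", B = 0))
  expect_true(all(abs(tab$auc[c(1, 2)] - 0.5) < 0.12))
})
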