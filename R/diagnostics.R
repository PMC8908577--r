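# Diagnostic-comparison machinery: logistic score models, ROC/AUC,
# sensitivity at fixed specificity, paired DeLong tests, subject-clustered
# bootstrap inference, and two-sample post-hoc power.

#' Multivariable binary logistic score model
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares (Newton-Raphson), with a tiny ridge term (default `1e-8`)
#' on the Hessian for numerical stability only.  The per-eye predicted
#' probabilities serve as diagnostic scores.
#'
#' @param x numeric feature matrix (eyes x features).
#' @param y binary outcome: logical or 0/1, `TRUE`/1 = case.
#' @param ridge ridge penalty added to the Hessian diagonal.
#' @param max_iter,tol iteration cap and gradient-norm convergence
#'   tolerance.
#' @param name optional model name.
#' @return object of class `score_model`: coefficients (intercept first),
#'   fitted probabilities (`scores`), convergence and separation flags.
#' @export
fit_logistic <- function(x, y, ridge = 1e-8, max_iter = 100, tol = 1e-6,
                         name = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  # center/scale internally for conditioning; coefficients mapped back
  mu <- c(0, colMeans(x)); sc <- c(1, apply(x, 2, stats::sd))
  sc[sc == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/"); Xs[, 1] <- 1
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xs %*% beta)
    prob <- stats::plogis(eta)
    g <- drop(crossprod(Xs, y - prob)) - ridge * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(prob * (1 - prob), 1e-12)
    H <- crossprod(Xs * w, Xs) + diag(ridge, p)
    beta <- beta + solve(H, g)
  }
  separation <- !converged && max(abs(beta)) > 15
  if (separation)
    warning("possible perfect separation; coefficients taken at iteration cap")
  else if (!converged)
    stop("logistic fit failed to converge", call. = FALSE)
  # back-transform to the original feature scale
  b <- beta / sc
  b[1] <- beta[1] - sum((beta[-1] * mu[-1]) / sc[-1])
  names(b) <- colnames(X)
  structure(list(coefficients = b, scores = stats::plogis(drop(X %*% b)),
                 converged = converged, separation = separation,
                 iterations = it, name = name, features = colnames(x)),
            class = "score_model")
}

#' @export
predict.score_model <- function(object, newdata, ...) {
  stats::plogis(drop(cbind(1, as.matrix(newdata)) %*% object$coefficients))
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("Logistic score model%s: %d features, %s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$coefficients) - 1,
              if (x$separation) "separated (capped)" else
                sprintf("converged in %d iterations", x$iterations)))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, with ties counting one half; computed from midranks, which
#' equals the brute-force mean over all case-control pairs.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels, `TRUE`/1 = case.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

#' Sensitivity at fixed specificity
#'
#' Maximum empirical sensitivity over all score thresholds whose
#' specificity is at least `specificity`, on the empirical ROC without
#' interpolation.
#'
#' @inheritParams roc_auc
#' @param specificity required specificity in `(0, 1]`.
#' @return sensitivity in percent.
#' @export
sensitivity_at_specificity <- function(scores, labels, specificity = 0.80) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present", call. = FALSE)
  cases <- scores[labels]; ctrls <- scores[!labels]
  thr <- c(sort(unique(scores)), Inf)
  best <- 0
  for (t in thr) {
    if (mean(ctrls < t) >= specificity)
      best <- max(best, mean(cases >= t))
  }
  100 * best
}

# placement values: for each case, fraction of controls it beats (ties 1/2)
placements <- function(scores, labels) {
  cases <- scores[labels]; ctrls <- scores[!labels]
  v10 <- vapply(cases, function(x)
    mean((x > ctrls) + 0.5 * (x == ctrls)), numeric(1))
  v01 <- vapply(ctrls, function(y)
    mean((cases > y) + 0.5 * (cases == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same eyes using
#' the DeLong variance of the AUC difference derived from placement values
#' (structural components), with a two-sided normal reference.
#'
#' @param scores_a,scores_b score vectors on the same eyes.
#' @param labels binary labels, `TRUE`/1 = case.
#' @return list with `auc_a`, `auc_b`, `z`, `p`, and `degenerate` (`TRUE`
#'   when the variance of the difference is zero, in which case `p = 1`).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(v) || v < 1e-15)
    return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p = 1, degenerate = TRUE))
  z <- (auc_a - auc_b) / sqrt(v)
  list(auc_a = auc_a, auc_b = auc_b, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Subject-clustered bootstrap
#'
#' Resamples subjects (clusters) with replacement, keeping all eyes of each
#' drawn subject, and recomputes a statistic on each resample; inference
#' then respects the correlation between fellow eyes.  The confidence
#' interval is the percentile interval of the bootstrap distribution.
#'
#' @param stat function taking a vector of row indices (eyes) and returning
#'   a scalar; called on each resample and once on the full data for the
#'   point estimate.
#' @param subjects subject identifier per eye (defines the clusters).
#' @param B number of bootstrap resamples.
#' @param seed optional integer seed (deterministic given the seed).
#' @param conf confidence level.
#' @return list with `estimate`, `ci` (lower/upper), `replicates`, and
#'   `n_redrawn` (resamples redrawn because the statistic was undefined,
#'   e.g. a single-class draw).
#' @export
clustered_bootstrap <- function(stat, subjects, B = 2000, seed = NULL,
                                conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  groups <- split(seq_along(subjects), subjects)
  if (length(groups) < 2) stop("need at least 2 subjects", call. = FALSE)
  est <- stat(seq_along(subjects))
  reps <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                    use.names = FALSE)
      val <- tryCatch(stat(idx), error = function(e) NA_real_)
      if (is.finite(val)) break
      redrawn <- redrawn + 1L
      if (redrawn > 50 * B) stop("statistic undefined on almost all resamples")
    }
    reps[b] <- val
  }
  alpha <- 1 - conf
  list(estimate = est,
       ci = unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2))),
       replicates = reps, n_redrawn = redrawn)
}

#' Post-hoc power for a two-sample mean comparison
#'
#' Normal-approximation power of a two-sided two-sample z-test with
#' unpooled variances:
#' `z = |mean1 - mean2| / sqrt(sd1^2/n1 + sd2^2/n2)`, and
#' `power = Phi(z - z_{1-alpha/2}) + Phi(-z - z_{1-alpha/2})`.
#'
#' @param mean1,sd1,n1 first group summary statistics.
#' @param mean2,sd2,n2 second group summary statistics.
#' @param alpha two-sided significance level.
#' @param pooled if `TRUE`, uses the pooled standard deviation instead.
#' @return power in percent.
#' @export
posthoc_power <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05,
                          pooled = FALSE) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  se <- if (pooled) {
    sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
    sp * sqrt(1 / n1 + 1 / n2)
  } else sqrt(sd1^2 / n1 + sd2^2 / n2)
  z <- abs(mean1 - mean2) / se
  za <- stats::qnorm(1 - alpha / 2)
  100 * (stats::pnorm(z - za) + stats::pnorm(-z - za))
}

comparison_features <- function(cohort, comp) {
  rnfl <- profile_matrix(cohort, "rnfl")
  vd <- profile_matrix(cohort, "vd")
  qmat <- function(m) t(apply(m, 1, function(p) quadrant_summary(p)[1:4]))
  mac_cols <- macular_cols()
  mac <- as.matrix(cohort[, mac_cols])
  mgcc <- sapply(ETDRS_SECTORS, function(s)
    mac[, paste0("mrnfl_", s)] + mac[, paste0("mgcl_", s)] +
      mac[, paste0("mipl_", s)])
  colnames(mgcc) <- paste0("mgcc_", ETDRS_SECTORS)
  ocular <- as.matrix(cohort[, c("disc_area", "disc_ratio", "disc_orientation",
                                 "fovea_distance", "fovea_angle",
                                 "refractive_error", "age")])
  comp_q <- qmat(comp)
  colnames(comp_q) <- paste0("comp_", colnames(comp_q))
  meas_q <- qmat(rnfl); colnames(meas_q) <- paste0("rnfl_", colnames(meas_q))
  vd_q <- qmat(vd); colnames(vd_q) <- paste0("vd_", colnames(vd_q))
  list(
    "Measured cpRNFL thickness" = meas_q,
    "Retinal vessel density" = vd_q,
    "Macular layers (mRNFL, mGCL and mIPL)" = mac,
    "Compensated cpRNFL thickness and ocular factors" = cbind(comp_q, ocular),
    "Combined (compensated + mGCC)" = cbind(comp_q, ocular, mgcc)
  )
}

#' Diagnostic comparison table
#'
#' Builds the five-way diagnostic comparison for a labeled cohort: logistic
#' score models on (1) measured cpRNFL quadrants, (2) vessel-density
#' quadrants, (3) macular mRNFL+mGCL+mIPL ETDRS sectors, (4) compensated
#' cpRNFL quadrants plus ocular factors, and (5) the combined model (4)
#' plus mGCC sectors.  Each row reports the in-sample AUC, a
#' subject-clustered bootstrap confidence interval (refitting the score
#' model on every resample), the sensitivity at fixed specificity, and the
#' paired DeLong p-value against the measured-cpRNFL reference row.
#'
#' @param cohort labeled cohort data.frame.
#' @param model fitted `rnfl_compensation` used to produce compensated
#'   profiles.
#' @param contrast which groups to compare; cases are the second-named
#'   class.
#' @param B bootstrap resamples for the AUC confidence interval (0 skips
#'   the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @param specificity specificity at which sensitivity is reported.
#' @return a `diagnostic_comparison` data.frame with one row per score
#'   model; score vectors and labels are attached as attributes.
#' @export
build_comparison <- function(cohort, model,
                             contrast = c("cases_vs_control", "mci_vs_control",
                                          "ad_vs_control", "mci_vs_ad"),
                             B = 2000, seed = 1, specificity = 0.80) {
  contrast <- match.arg(contrast)
  sel <- switch(contrast,
    cases_vs_control = list(keep = c("control", "mci", "ad"),
                            case = c("mci", "ad")),
    mci_vs_control = list(keep = c("control", "mci"), case = "mci"),
    ad_vs_control = list(keep = c("control", "ad"), case = "ad"),
    mci_vs_ad = list(keep = c("mci", "ad"), case = "ad"))
  cohort <- cohort[cohort$group %in% sel$keep, ]
  labels <- cohort$group %in% sel$case
  if (!any(labels) || all(labels))
    stop("contrast has an empty class", call. = FALSE)
  comp <- predict(model, cohort)
  feats <- comparison_features(cohort, comp)

  scores <- lapply(names(feats), function(nm)
    fit_logistic(feats[[nm]], labels, name = nm)$scores)
  names(scores) <- names(feats)
  ref <- scores[[1]]

  rows <- lapply(seq_along(feats), function(i) {
    sc <- scores[[i]]
    auc <- roc_auc(sc, labels)
    ci <- c(NA_real_, NA_real_)
    if (B > 0) {
      bs <- clustered_bootstrap(function(idx) {
        y <- labels[idx]
        if (!any(y) || all(y)) return(NA_real_)
        f <- suppressWarnings(
          fit_logistic(feats[[i]][idx, , drop = FALSE], y))
        roc_auc(f$scores, y)
      }, cohort$subject_id, B = B, seed = seed + i)
      ci <- bs$ci
    }
    dl_p <- if (i == 1) NA_real_ else delong_test(sc, ref, labels)$p
    data.frame(parameter = names(feats)[i],
               n_features = ncol(feats[[i]]),
               auc = auc, ci_lower = ci[1], ci_upper = ci[2],
               sens_at_spec = sensitivity_at_specificity(sc, labels,
                                                         specificity),
               delong_p = dl_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "contrast") <- contrast
  attr(out, "specificity") <- specificity
  attr(out, "scores") <- scores
  attr(out, "labels") <- labels
  class(out) <- c("diagnostic_comparison", "data.frame")
  out
}

#' @export
print.diagnostic_comparison <- function(x, ...) {
  cat("Diagnostic comparison:", attr(x, "contrast"), "\n")
  spec <- attr(x, "specificity")
  for (i in seq_len(nrow(x))) {
    ci <- if (is.na(x$ci_lower[i])) "" else
      sprintf(" (%.2f-%.2f)", x$ci_lower[i], x$ci_upper[i])
    p <- if (is.na(x$delong_p[i])) "Ref" else sprintf("p=%.3f", x$delong_p[i])
    cat(sprintf("  %d. %-48s AUC %.2f%s  sens@%.0f%%spec %.1f  %s\n",
                i, x$parameter[i], x$auc[i], ci, 100 * spec,
                x$sens_at_spec[i], p))
  }
  invisible(x)
}

#' @export
plot.diagnostic_comparison <- function(x, ...) {
  scores <- attr(x, "scores"); labels <- attr(x, "labels")
  cols <- grDevices::hcl.colors(length(scores), "Dark 2")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = attr(x, "contrast"))
  for (i in seq_along(scores)) {
    sc <- scores[[i]]
    thr <- c(-Inf, sort(unique(sc)), Inf)
    fpr <- vapply(thr, function(t) mean(sc[!labels] >= t), numeric(1))
    tpr <- vapply(thr, function(t) mean(sc[labels] >= t), numeric(1))
    graphics::lines(fpr, tpr, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols, cex = 0.7,
                   legend = sprintf("%s (AUC %.2f)", x$parameter, x$auc))
  invisible(x)
}
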