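# Per-sector AIC-selected multivariate linear regression of measured
# cpRNFL thickness on ocular/demographic covariates, and the subtraction
# of the selected centered covariate effects ("compensation").

COMP_CANDIDATES <- c("age", "ethnicity", "refractive_error", "signal_strength",
                     "disc_area", "disc_ratio", "disc_orientation",
                     "fovea_distance", "fovea_angle", "vessel_density")

#' Gaussian AIC from a residual sum of squares
#'
#' `AIC = n * log(rss / n) + 2 * (k + 1)`: the Gaussian log-likelihood at
#' the OLS fit up to an additive constant, with the residual variance
#' counted as an extra parameter.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of observations.
#' @param k number of fitted mean parameters (including the intercept).
#' @return the AIC value; an exact fit (`rss == 0`) returns `-Inf` with
#'   attribute `exact_fit = TRUE`.
#' @export
aic_gaussian <- function(rss, n, k) {
  stopifnot(n > k, rss >= 0)
  if (rss == 0) return(structure(-Inf, exact_fit = TRUE))
  n * log(rss / n) + 2 * (k + 1)
}

# Design columns for the non-vessel candidates.  Ethnicity enters as
# reference-coded indicators treated as a single selectable unit.
build_base_design <- function(cohort, candidates, eth_levels = NULL) {
  cols <- list(); unit_cols <- list()
  add <- function(unit, m) {
    start <- sum(vapply(cols, ncol, 0L)) + 1L
    cols[[unit]] <<- m
    unit_cols[[unit]] <<- start:(start + ncol(m) - 1L)
  }
  for (u in candidates) {
    if (u == "vessel_density") next
    if (u == "ethnicity") {
      eth <- factor(cohort$ethnicity, levels = eth_levels %||%
                      sort(unique(cohort$ethnicity)))
      if (nlevels(eth) < 2) next
      mm <- stats::model.matrix(~eth)[, -1, drop = FALSE]
      colnames(mm) <- paste0("ethnicity_", levels(eth)[-1])
      add(u, mm)
    } else {
      m <- matrix(cohort[[u]], ncol = 1, dimnames = list(NULL, u))
      add(u, m)
    }
  }
  Z <- do.call(cbind, unname(cols))
  list(Z = Z, unit_cols = unit_cols,
       eth_levels = if ("ethnicity" %in% names(unit_cols))
         levels(factor(cohort$ethnicity, levels = eth_levels %||%
                         sort(unique(cohort$ethnicity)))) else NULL)
}

vd_design <- function(cohort, vd_mode) {
  V <- profile_matrix(cohort, "vd")
  if (vd_mode == "quadrant") {
    for (q in QUADRANTS) V[, q] <- rowMeans(V[, q, drop = FALSE])
  }
  V
}

#' Fit the per-sector cpRNFL compensation model
#'
#' For each of the 256 circumpapillary sectors, fits ordinary least squares
#' regressions of measured thickness on subsets of the candidate covariates
#' (optic disc area/ratio/orientation, fovea distance/angle, the sector's
#' own vessel density, refractive error, age, ethnicity and signal
#' strength) and keeps the subset minimizing the Gaussian AIC.  The model
#' is intended to be trained on control-group eyes.
#'
#' @param cohort cohort data.frame (one row per eye).
#' @param candidates candidate covariate units; ethnicity is selected
#'   in/out as a whole factor.
#' @param selection `"exhaustive"` enumerates all covariate subsets (up to
#'   12 units); `"forward"` is greedy stepwise addition.
#' @param train_group group label used for training (default `"control"`);
#'   `NULL` uses all rows.
#' @param vd_mode `"sector"` couples each sector to its own vessel density;
#'   `"quadrant"` uses the quadrant-mean density.
#' @return an object of class `rnfl_compensation` with per-sector selected
#'   covariates, coefficients, training means/SDs and AIC; see
#'   [predict.rnfl_compensation()].
#' @export
fit_compensation <- function(cohort,
                             candidates = COMP_CANDIDATES,
                             selection = c("exhaustive", "forward"),
                             train_group = "control",
                             vd_mode = c("sector", "quadrant")) {
  selection <- match.arg(selection)
  vd_mode <- match.arg(vd_mode)
  if (length(candidates) > 0)
    candidates <- match.arg(candidates, COMP_CANDIDATES, several.ok = TRUE)
  if (!is.null(train_group)) cohort <- cohort[cohort$group %in% train_group, ]
  n <- nrow(cohort)
  if (n < 30) stop("need at least 30 training eyes, got ", n, call. = FALSE)

  bd <- build_base_design(cohort, candidates)
  Z <- bd$Z; unit_cols <- bd$unit_cols
  # drop constant covariates (rank-deficient design) with a warning
  if (!is.null(Z)) {
    bad <- names(Filter(function(ix) any(apply(Z[, ix, drop = FALSE], 2,
                                               stats::sd) == 0), unit_cols))
    if (length(bad) > 0) {
      warning("dropping constant covariate(s): ", paste(bad, collapse = ", "))
      keep <- !colnames(Z) %in% unlist(lapply(bad, function(u)
        colnames(Z)[unit_cols[[u]]]))
      Z <- Z[, keep, drop = FALSE]
      bd <- build_base_design(cohort, setdiff(candidates, c(bad, "vessel_density")),
                              bd$eth_levels)
      Z <- bd$Z; unit_cols <- bd$unit_cols
      candidates <- setdiff(candidates, bad)
    }
  }
  use_vd <- "vessel_density" %in% candidates
  pz <- if (is.null(Z)) 0L else ncol(Z)
  p <- pz + as.integer(use_vd)
  col_names <- c(if (pz > 0) colnames(Z), if (use_vd) "vessel_density")
  units <- c(names(unit_cols), if (use_vd) "vessel_density")
  K <- length(units)
  if (K == 0 && selection == "exhaustive") selection <- "forward"  # no-op
  if (selection == "exhaustive" && K > 12)
    stop("exhaustive search limited to 12 candidate units; use forward")
  # column indices (within the p design columns) per unit
  ucols <- c(unit_cols, if (use_vd) list(vessel_density = p))
  names(ucols) <- units
  if (n <= p + 3) stop("too few training eyes for the candidate set")

  Y <- profile_matrix(cohort, "rnfl")
  V <- if (use_vd) vd_design(cohort, vd_mode) else NULL

  # precompute subset index vectors into the bordered Gram matrix
  # M = [1 | design | y]; intercept is column 1, y is column p + 2.
  ycol <- p + 2L
  subset_masks <- if (selection == "exhaustive") {
    lapply(0:(2^K - 1), function(m) as.logical(bitwAnd(m, 2^(seq_len(K) - 1)) > 0))
  } else NULL
  subset_idx <- if (!is.null(subset_masks)) {
    lapply(subset_masks, function(msk)
      c(1L, unlist(ucols[msk], use.names = FALSE) + 1L))
  } else NULL

  sel <- matrix(FALSE, N_SECTORS, K, dimnames = list(NULL, units))
  coefm <- matrix(0, N_SECTORS, p, dimnames = list(NULL, col_names))
  xbar <- matrix(0, N_SECTORS, p, dimnames = list(NULL, col_names))
  xsd <- matrix(0, N_SECTORS, p, dimnames = list(NULL, col_names))
  intercept <- aic_vec <- numeric(N_SECTORS)

  zbar <- if (pz > 0) colMeans(Z) else numeric(0)
  zsd <- if (pz > 0) apply(Z, 2, stats::sd) else numeric(0)

  for (s in seq_len(N_SECTORS)) {
    X <- if (use_vd) cbind(Z, V[, s]) else Z
    y <- Y[, s]
    M <- cbind(1, X, y)
    G <- crossprod(M)
    yty <- G[ycol, ycol]

    eval_subset <- function(idx) {
      A <- G[idx, idx, drop = FALSE]
      rhs <- G[idx, ycol]
      beta <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(beta)) return(NULL)
      rss <- max(yty - sum(beta * rhs), 0)
      k <- length(idx)
      a <- if (rss <= 1e-10 * yty)
        structure(-Inf, exact_fit = TRUE) else n * log(rss / n) + 2 * (k + 1)
      list(aic = a, beta = beta, idx = idx)
    }

    if (selection == "exhaustive") {
      best <- NULL; best_mask <- NULL
      for (j in seq_along(subset_idx)) {
        f <- eval_subset(subset_idx[[j]])
        if (!is.null(f) && (is.null(best) || f$aic < best$aic)) {
          best <- f; best_mask <- subset_masks[[j]]
        }
      }
    } else {
      cur_mask <- rep(FALSE, K)
      best <- eval_subset(1L)
      repeat {
        improved <- FALSE
        for (u in which(!cur_mask)) {
          msk <- cur_mask; msk[u] <- TRUE
          idx <- c(1L, unlist(ucols[msk], use.names = FALSE) + 1L)
          f <- eval_subset(idx)
          if (!is.null(f) && f$aic < best$aic) {
            best <- f; cur_mask_new <- msk; improved <- TRUE
          }
        }
        if (!improved) break
        cur_mask <- cur_mask_new
      }
      best_mask <- cur_mask
    }

    sel[s, ] <- best_mask
    intercept[s] <- best$beta[1]
    if (length(best$idx) > 1)
      coefm[s, best$idx[-1] - 1L] <- best$beta[-1]
    aic_vec[s] <- best$aic
    if (pz > 0) { xbar[s, 1:pz] <- zbar; xsd[s, 1:pz] <- zsd }
    if (use_vd) { xbar[s, p] <- mean(V[, s]); xsd[s, p] <- stats::sd(V[, s]) }
  }

  structure(list(
    candidates = units, unit_cols = ucols, col_names = col_names,
    eth_levels = bd$eth_levels,
    selected = sel, coefficients = coefm, intercept = intercept,
    xbar = xbar, xsd = xsd, aic = aic_vec,
    n_train = n, selection = selection, vd_mode = vd_mode,
    train_group = train_group
  ), class = "rnfl_compensation")
}

# design columns of new data in the layout of a fitted model
design_for <- function(object, cohort) {
  cand <- setdiff(object$candidates, "vessel_density")
  Z <- if (length(cand) > 0)
    build_base_design(cohort, cand, object$eth_levels)$Z else NULL
  V <- if ("vessel_density" %in% object$candidates)
    vd_design(cohort, object$vd_mode) else NULL
  list(Z = Z, V = V)
}

#' Apply the compensation model to eyes
#'
#' The compensated profile of an eye is
#' `compensated(s) = measured(s) - sum_k beta_k(s) * (x_k - xbar_k(s))`:
#' the selected covariate effects, centered at the training means, are
#' subtracted sector by sector.  An eye whose covariates sit exactly at the
#' training means is returned unchanged, and the training-set mean
#' thickness is preserved per sector.
#'
#' @param object a fitted `rnfl_compensation` model.
#' @param newdata cohort data.frame of eyes to compensate.
#' @param ... unused.
#' @return numeric matrix (eyes x 256) of compensated thicknesses with
#'   attribute `extrapolated`: logical vector flagging eyes with any
#'   covariate beyond 6 training SDs.
#' @export
predict.rnfl_compensation <- function(object, newdata, ...) {
  d <- design_for(object, newdata)
  Y <- profile_matrix(newdata, "rnfl")
  n <- nrow(Y)
  p <- length(object$col_names)
  pz <- p - as.integer("vessel_density" %in% object$candidates)
  B <- object$coefficients
  adj <- matrix(0, n, N_SECTORS)
  if (pz > 0) {
    Bz <- B[, 1:pz, drop = FALSE]
    adj <- d$Z %*% t(Bz) -
      matrix(rowSums(Bz * object$xbar[, 1:pz, drop = FALSE]),
             n, N_SECTORS, byrow = TRUE)
  }
  if (!is.null(d$V)) {
    bvd <- B[, p]
    adj <- adj + sweep(d$V, 2, object$xbar[, p]) *
      matrix(bvd, n, N_SECTORS, byrow = TRUE)
  }
  out <- Y - adj
  # extrapolation check against training spread
  extra <- rep(FALSE, n)
  if (pz > 0) {
    zb <- object$xbar[1, 1:pz]; zs <- object$xsd[1, 1:pz]
    ok <- zs > 0
    if (any(ok)) {
      zz <- abs(sweep(sweep(d$Z[, ok, drop = FALSE], 2, zb[ok]), 2, zs[ok], "/"))
      extra <- extra | apply(zz > 6, 1, any)
    }
  }
  if (!is.null(d$V)) {
    zz <- abs(sweep(sweep(d$V, 2, object$xbar[, p]), 2,
                    pmax(object$xsd[, p], 1e-12), "/"))
    extra <- extra | apply(zz > 6, 1, any)
  }
  if (any(extra))
    warning(sum(extra), " eye(s) outside 6 training SDs; ",
            "compensation is an extrapolation there")
  attr(out, "extrapolated") <- extra
  out
}

#' @rdname predict.rnfl_compensation
#' @param model a fitted `rnfl_compensation` model.
#' @param eyes cohort data.frame of eyes to compensate.
#' @export
compensate <- function(eyes, model) predict(model, eyes)

#' Vessel-density decorrelation check
#'
#' Pearson correlations, across eyes, between mean vessel density and mean
#' measured vs compensated cpRNFL thickness.  On a confounded cohort the
#' compensated correlation should shrink toward zero.
#'
#' @param cohort cohort data.frame with at least 50 eyes.
#' @param model fitted `rnfl_compensation`.
#' @return list with `r_measured`, `r_compensated`, and the corresponding
#'   `p_measured`, `p_compensated` from [stats::cor.test()].
#' @export
decorrelation_check <- function(cohort, model) {
  if (nrow(cohort) < 50) stop("need at least 50 eyes", call. = FALSE)
  gvd <- rowMeans(profile_matrix(cohort, "vd"))
  gme <- rowMeans(profile_matrix(cohort, "rnfl"))
  gco <- rowMeans(predict(model, cohort))
  if (stats::sd(gvd) == 0 || stats::sd(gme) == 0)
    stop("zero-variance input", call. = FALSE)
  tm <- stats::cor.test(gvd, gme)
  tc <- stats::cor.test(gvd, gco)
  list(r_measured = unname(tm$estimate), r_compensated = unname(tc$estimate),
       p_measured = tm$p.value, p_compensated = tc$p.value)
}

#' @export
print.rnfl_compensation <- function(x, ...) {
  cat("Per-sector cpRNFL compensation model\n")
  cat(sprintf("  sectors: %d, training eyes: %d (%s), selection: %s\n",
              N_SECTORS, x$n_train,
              paste(x$train_group %||% "all", collapse = "/"), x$selection))
  cat(sprintf("  candidates: %s\n", paste(x$candidates, collapse = ", ")))
  cat(sprintf("  mean selected covariates per sector: %.2f\n",
              mean(rowSums(x$selected))))
  invisible(x)
}

#' @export
summary.rnfl_compensation <- function(object, ...) {
  freq <- colMeans(object$selected)
  out <- list(selection_frequency = freq,
              mean_aic = mean(object$aic[is.finite(object$aic)]),
              n_train = object$n_train,
              mean_model_size = mean(rowSums(object$selected)))
  class(out) <- "summary.rnfl_compensation"
  out
}

#' @export
print.summary.rnfl_compensation <- function(x, ...) {
  cat("Compensation model summary\n")
  cat(sprintf("  training eyes: %d, mean AIC: %.1f, mean model size: %.2f\n",
              x$n_train, x$mean_aic, x$mean_model_size))
  cat("  selection frequency across sectors:\n")
  print(round(x$selection_frequency, 3))
  invisible(x)
}

#' @export
coef.rnfl_compensation <- function(object, ...) object$coefficients

#' @export
plot.rnfl_compensation <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(colMeans(x$selected), las = 2, cex.names = 0.7,
                    ylab = "selection frequency",
                    main = "AIC covariate selection across sectors")
  if ("vessel_density" %in% x$col_names) {
    b <- x$coefficients[, "vessel_density"]
    graphics::plot(0:255, b, type = "h", xlab = "sector",
                   ylab = "coefficient (um per density unit)",
                   main = "vessel-density coefficient profile")
  } else {
    graphics::plot(0:255, x$aic, type = "l", xlab = "sector", ylab = "AIC")
  }
  invisible(x)
}

#' Serialize / restore a compensation model as JSON
#'
#' Versioned plain-text serialization of the per-sector covariate
#' selection, coefficients, training means/SDs and AIC values.
#'
#' @param model fitted `rnfl_compensation`.
#' @param path file path.
#' @return `read_compensation` returns the restored `rnfl_compensation`.
#' @export
write_compensation <- function(model, path) {
  payload <- list(
    schema_version = 1L,
    candidates = model$candidates,
    unit_cols = model$unit_cols,
    col_names = model$col_names,
    eth_levels = model$eth_levels,
    selected = model$selected,
    coefficients = model$coefficients,
    intercept = model$intercept,
    xbar = model$xbar, xsd = model$xsd, aic = model$aic,
    n_train = model$n_train, selection = model$selection,
    vd_mode = model$vd_mode, train_group = model$train_group
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_compensation
#' @export
read_compensation <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) || p$schema_version != 1)
    stop("unsupported compensation model schema", call. = FALSE)
  for (m in c("selected", "coefficients", "xbar", "xsd"))
    colnames(p[[m]]) <- if (m == "selected") p$candidates else p$col_names
  p$selected <- p$selected == 1 | p$selected == TRUE
  p$unit_cols <- lapply(p$unit_cols, as.integer)
  keep <- c("candidates", "unit_cols", "col_names", "eth_levels", "selected",
            "coefficients", "intercept", "xbar", "xsd", "aic", "n_train",
            "selection", "vd_mode", "train_group")
  structure(p[keep], class = "rnfl_compensation")
}
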