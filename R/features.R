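# Feature extraction from en-face images and sector profiles: vessel
# segmentation, annular 256-sector vessel density, disc ellipse
# morphometry, fovea geometry, quadrant summaries and ETDRS macular
# composites.

otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  EBImage::otsu(matrix(x, nrow = 1), range = range(x), levels = 256)
}

#' Segment vessels in an en-face image
#'
#' Vessels are assumed to be the darkest intensity tier of the image (below
#' both the background and the disc).  With no explicit threshold, a
#' two-stage Otsu rule is used: a first threshold separates the dark
#' structures (disc, fovea, vessels) from the background, and a second
#' threshold inside the dark class isolates the vessel tier.  If the dark
#' class is itself homogeneous it is taken to be all vessel.
#'
#' @param img an `enface_image` or a numeric matrix in `[0, 1]`.
#' @param threshold optional fixed intensity threshold; pixels at or below
#'   it are vessel (after polarity handling).
#' @param polarity `"dark"` (default) if vessels are darker than background,
#'   `"bright"` otherwise.
#' @return logical matrix (`TRUE` = vessel).  A flat image yields an
#'   all-`FALSE` map with a warning.
#' @export
segment_vessels <- function(img, threshold = NULL, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  px <- if (inherits(img, "enface_image")) img$pixels else img
  stopifnot(is.matrix(px))
  if (polarity == "bright") px <- 1 - px
  rng <- range(px)
  if (diff(rng) < 1e-8) {
    warning("image has no dynamic range; returning empty vessel map")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  if (!is.null(threshold)) return(px <= threshold)
  t1 <- otsu_threshold(px)
  dark <- px[px <= t1]
  if (diff(range(dark)) < 1e-3) return(px <= t1)
  t2 <- otsu_threshold(dark)
  px <= t2
}

#' Annular 256-sector vessel density
#'
#' Integrates a binary vessel map over a band around the optic disc center
#' (default diameters 3.28-3.64 mm, i.e. radii 1.64-1.82 mm), split into
#' 256 equiangular sectors starting at the temporal horizontal meridian and
#' proceeding superiorly.  Density is the vessel-positive pixel fraction of
#' each annulus wedge.
#'
#' @param vessel_map logical matrix (`TRUE` = vessel).
#' @param disc_center numeric `c(x, y)` in mm (image frame, y downward).
#' @param pixel_scale mm per pixel.
#' @param radii inner and outer band radii in mm.
#' @param laterality `"right"` or `"left"`; left-eye maps are evaluated in
#'   the mirrored (normalized right-eye) frame.
#' @return numeric vector of 256 sector densities in `[0, 1]`; wedges that
#'   contain no pixel at the given scale are `NA` with a warning.
#' @export
sector_vessel_density <- function(vessel_map, disc_center, pixel_scale,
                                  radii = c(1.64, 1.82),
                                  laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(is.matrix(vessel_map), length(disc_center) == 2)
  ny <- nrow(vessel_map); nx <- ncol(vessel_map)
  if (disc_center[1] - radii[2] < 0 || disc_center[1] + radii[2] > nx * pixel_scale ||
      disc_center[2] - radii[2] < 0 || disc_center[2] + radii[2] > ny * pixel_scale)
    stop("annulus (outer radius ", radii[2],
         " mm) is clipped by the image border", call. = FALSE)
  g <- pixel_grid(nx, ny, pixel_scale)
  dx <- g$x - disc_center[1]
  dy <- g$y - disc_center[2]
  if (laterality == "left") dx <- -dx
  r <- sqrt(dx^2 + dy^2)
  inband <- r >= radii[1] & r < radii[2]
  theta <- atan2(-dy[inband], dx[inband]) %% (2 * pi)
  sec <- angle_to_sector(theta)
  tot <- tabulate(sec, nbins = N_SECTORS)
  ves <- tabulate(sec[vessel_map[inband]], nbins = N_SECTORS)
  if (any(tot == 0))
    warning("pixel scale too coarse: ", sum(tot == 0),
            " empty annulus wedge(s) return NA")
  ifelse(tot > 0, ves / tot, NA_real_)
}

# Convert area-fraction densities to the cohort density scale using the
# renderer's caliber calibration: fraction ~= width / (arc at mid-radius).
fraction_to_density_units <- function(frac, caliber_per_unit,
                                      radii = c(1.64, 1.82)) {
  arc_mid <- mean(radii) * 2 * pi / N_SECTORS
  frac * arc_mid / caliber_per_unit
}

#' Optic disc ellipse morphometry
#'
#' Fits an ellipse to a binary disc mask by second moments: the area is the
#' pixel area, the orientation is the angle between the horizontal axis and
#' the major axis (degrees in `[0, 180)`, measured toward the superior
#' direction), and the ratio is the major/minor axis quotient.  A near
#' circular fit (axis ratio within 0.5% of 1) has no meaningful major axis;
#' its orientation is reported as 90 degrees with `degenerate = TRUE`.
#'
#' @param disc_mask logical matrix (`TRUE` = disc).
#' @param pixel_scale mm per pixel.
#' @return list with `area` (mm^2), `ratio`, `orientation` (degrees) and
#'   `degenerate`.
#' @export
fit_disc_ellipse <- function(disc_mask, pixel_scale) {
  stopifnot(is.matrix(disc_mask))
  if (!any(disc_mask)) stop("empty disc mask", call. = FALSE)
  lab <- EBImage::bwlabel(disc_mask)
  ncomp <- max(lab)
  if (ncomp > 1) {
    warning("disc mask has ", ncomp, " components; using the largest")
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    disc_mask <- lab == which.max(sizes)
  }
  idx <- which(disc_mask, arr.ind = TRUE)
  x <- (idx[, "col"] - 0.5) * pixel_scale
  yup <- -(idx[, "row"] - 0.5) * pixel_scale   # superior = +y
  area <- nrow(idx) * pixel_scale^2
  cv <- stats::cov(cbind(x, yup)) * (nrow(idx) - 1) / nrow(idx)
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 1e-12)
  ratio <- sqrt(lam[1] / lam[2])
  degenerate <- ratio < 1.005
  orientation <- if (degenerate) 90 else
    (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  list(area = area, ratio = ratio, orientation = orientation,
       degenerate = degenerate)
}

#' Fovea geometry relative to the optic disc
#'
#' Euclidean disc-fovea distance (mm) and the signed angle between the
#' disc-fovea line and the horizontal through the disc center, in the
#' normalized right-eye frame (temporal = towards the fovea); negative
#' angles mean the fovea sits inferior to the disc center.
#'
#' @param disc_center,fovea_center numeric `c(x, y)` in mm, image frame
#'   (y downward).
#' @param laterality `"right"`, `"left"`, or `"auto"` (infer from the sign
#'   of the horizontal disc-to-fovea offset).
#' @return list with `distance` (mm) and `angle` (degrees, signed).
#' @export
fovea_metrics <- function(disc_center, fovea_center, laterality = "auto") {
  dx <- fovea_center[1] - disc_center[1]
  dy <- fovea_center[2] - disc_center[2]
  if (abs(dx) < 1e-9 && abs(dy) < 1e-9)
    stop("disc and fovea centers coincide", call. = FALSE)
  if (laterality == "auto") laterality <- if (dx >= 0) "right" else "left"
  if (laterality == "left") dx <- -dx
  list(distance = sqrt(dx^2 + dy^2),
       angle = atan2(-dy, dx) * 180 / pi,
       laterality = laterality)
}

#' Quadrant and global summary of a sector profile
#'
#' Means over the four contiguous 64-sector quadrants (temporal, superior,
#' nasal, inferior, in index order) and the global mean of all 256 sectors.
#'
#' @param profile numeric vector of length 256.
#' @return named numeric vector `temporal`, `superior`, `nasal`,
#'   `inferior`, `global`.
#' @export
quadrant_summary <- function(profile) {
  stopifnot(length(profile) == N_SECTORS)
  q <- vapply(QUADRANTS, function(ix) mean(profile[ix]), numeric(1))
  c(q, global = mean(profile))
}

#' ETDRS macular composites
#'
#' Adds the ganglion cell complex (mGCC = mRNFL + mGCL + mIPL) and the
#' ganglion cell/inner plexiform composite (mGC-IPL = mGCL + mIPL) for each
#' of the 9 ETDRS sectors.
#'
#' @param macular a named numeric vector, list, or data.frame containing
#'   columns `mrnfl_<sector>`, `mgcl_<sector>`, `mipl_<sector>` for all 9
#'   ETDRS sectors.
#' @return the input with added `mgcc_<sector>` and `mgcipl_<sector>`
#'   entries.
#' @export
etdrs_composites <- function(macular) {
  is_df <- is.data.frame(macular)
  get_col <- function(nm) {
    if (is_df) {
      if (!nm %in% names(macular)) stop("missing macular input: ", nm, call. = FALSE)
      macular[[nm]]
    } else {
      if (is.null(macular[[nm]])) stop("missing macular input: ", nm, call. = FALSE)
      macular[[nm]]
    }
  }
  out <- macular
  for (s in ETDRS_SECTORS) {
    rnfl <- get_col(paste0("mrnfl_", s))
    gcl <- get_col(paste0("mgcl_", s))
    ipl <- get_col(paste0("mipl_", s))
    if (is_df || is.list(out)) {
      out[[paste0("mgcc_", s)]] <- rnfl + gcl + ipl
      out[[paste0("mgcipl_", s)]] <- gcl + ipl
    } else {
      out[paste0("mgcc_", s)] <- rnfl + gcl + ipl
      out[paste0("mgcipl_", s)] <- gcl + ipl
    }
  }
  out
}

#' Extract ocular features from an en-face image
#'
#' Full feature extraction for one image: segments the dark structures,
#' identifies the disc (largest dark non-vessel component) and fovea
#' (farthest dark component from the disc), fits the disc ellipse, computes
#' fovea geometry and the annular 256-sector vessel density, all in the
#' normalized right-eye frame (left eyes are mirrored before extraction).
#'
#' @param img an `enface_image` (rendered or read from disk).
#' @return list with `disc` (area/ratio/orientation), `fovea`
#'   (distance/angle), `laterality`, `vd_fraction` (area-fraction profile)
#'   and, when the calibration is available, `vd` on the cohort density
#'   scale.
#' @export
extract_features <- function(img) {
  stopifnot(inherits(img, "enface_image"))
  px <- img$pixels
  scale <- img$pixel_scale
  vessels <- segment_vessels(px)
  t1 <- otsu_threshold(px)
  blobs <- (px <= t1) & !vessels
  lab <- EBImage::bwlabel(blobs)
  ncomp <- max(lab)
  if (ncomp < 2)
    stop("could not locate both disc and fovea landmarks", call. = FALSE)
  cent <- matrix(NA_real_, ncomp, 2)
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    cent[k, ] <- c(mean(idx[, "col"]) - 0.5, mean(idx[, "row"]) - 0.5) * scale
  }
  disc_k <- which.max(sizes)
  d2 <- (cent[, 1] - cent[disc_k, 1])^2 + (cent[, 2] - cent[disc_k, 2])^2
  d2[sizes < 9] <- -Inf
  fov_k <- which.max(d2)
  disc_center <- cent[disc_k, ]
  fovea_center <- cent[fov_k, ]

  lat <- if (fovea_center[1] >= disc_center[1]) "right" else "left"
  disc_mask <- lab == disc_k
  if (lat == "left") disc_mask <- disc_mask[, ncol(disc_mask):1]
  disc <- fit_disc_ellipse(disc_mask, scale)
  fov <- fovea_metrics(disc_center, fovea_center, lat)
  vdf <- sector_vessel_density(vessels, disc_center, scale,
                               radii = img$config$annulus_radii,
                               laterality = lat)
  out <- list(disc = disc,
              fovea = fov[c("distance", "angle")],
              laterality = lat,
              vd_fraction = vdf,
              disc_center = disc_center, fovea_center = fovea_center)
  cal <- img$config$caliber_per_unit
  if (!is.null(cal))
    out$vd <- fraction_to_density_units(vdf, cal, img$config$annulus_radii)
  out
}
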