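# Synthetic en-face image rendering: a stitched disc+macula grayscale
# canvas with a dark elliptical optic disc, radial peripapillary vessels
# whose annular sector densities are controlled by the eye's
# vessel-density profile, and a fovea landmark.

#' En-face rendering configuration
#'
#' @param pixel_scale isotropic pixel size in mm per pixel.
#' @param width_mm,height_mm canvas extent in mm (must cover disc annulus
#'   and fovea).
#' @param disc_margin_mm distance from the nasal canvas edge to the disc
#'   center.
#' @param background,disc_gray,fovea_gray,vessel_gray intensity levels in
#'   `[0, 1]`; vessels must be the darkest tier for segmentation.
#' @param caliber_per_unit vessel caliber in mm per unit of sector density;
#'   converts the dimensionless cohort density scale into spoke widths.
#' @param annulus_radii inner/outer radii (mm) of the vessel-density band
#'   (diameters 3.28-3.64 mm around the disc center).
#' @param vessel_extent_mm outermost radius to which vessels are drawn.
#' @param fovea_radius_mm radius of the rendered fovea landmark.
#' @return a list of class `image_config`.
#' @export
image_config <- function(pixel_scale = 0.01, width_mm = 9, height_mm = 6,
                         disc_margin_mm = 2.2,
                         background = 0.85, disc_gray = 0.45,
                         fovea_gray = 0.45, vessel_gray = 0.05,
                         caliber_per_unit = 0.008,
                         annulus_radii = c(1.64, 1.82),
                         vessel_extent_mm = 2.6,
                         fovea_radius_mm = 0.12) {
  stopifnot_scalar(pixel_scale, "pixel_scale", 1e-5)
  stopifnot(length(annulus_radii) == 2, annulus_radii[1] < annulus_radii[2])
  structure(list(pixel_scale = pixel_scale, width_mm = width_mm,
                 height_mm = height_mm, disc_margin_mm = disc_margin_mm,
                 background = background, disc_gray = disc_gray,
                 fovea_gray = fovea_gray, vessel_gray = vessel_gray,
                 caliber_per_unit = caliber_per_unit,
                 annulus_radii = annulus_radii,
                 vessel_extent_mm = vessel_extent_mm,
                 fovea_radius_mm = fovea_radius_mm),
            class = "image_config")
}

# Pixel-center coordinate grids in mm.  Images are matrices indexed
# [row, col] with x = (col - 0.5) * scale (rightward) and
# y = (row - 0.5) * scale (downward); the superior retinal direction is -y.
pixel_grid <- function(nx, ny, scale) {
  list(x = matrix((seq_len(nx) - 0.5) * scale, ny, nx, byrow = TRUE),
       y = matrix((seq_len(ny) - 0.5) * scale, ny, nx))
}

#' Render a synthetic en-face image for one eye
#'
#' Draws the eye's optic disc as a filled ellipse with the configured area,
#' axis ratio and orientation, a set of radial vessels (one spoke per
#' sector, caliber proportional to the sector's vessel density so that
#' annular sector area fractions are proportional to the eye's density
#' profile), and a fovea landmark at the eye's fovea distance and angle.
#' Left eyes are rendered mirrored about the vertical axis; sector profiles
#' are interpreted in the normalized right-eye orientation.
#'
#' @param eye a single-row cohort data.frame (see [generate_cohort()]) or a
#'   list with fields `eye`, `disc_area`, `disc_ratio`, `disc_orientation`,
#'   `fovea_distance`, `fovea_angle` and a 256-vector `vd`.
#' @param config an [image_config()].
#' @return an object of class `enface_image`: list with `pixels` (matrix in
#'   `[0,1]`), `pixel_scale`, `disc_center` and `fovea_center` (mm, image
#'   frame, xy order), `laterality`, ground-truth `vessel_mask` and
#'   `disc_mask`, and the rendering `config`.
#' @export
render_enface <- function(eye, config = image_config()) {
  cfg <- config
  if (is.data.frame(eye)) {
    stopifnot(nrow(eye) == 1)
    vd <- as.numeric(eye[1, sector_cols("vd")])
    eye <- list(eye = eye$eye[1], disc_area = eye$disc_area[1],
                disc_ratio = eye$disc_ratio[1],
                disc_orientation = eye$disc_orientation[1],
                fovea_distance = eye$fovea_distance[1],
                fovea_angle = eye$fovea_angle[1], vd = vd)
  }
  stopifnot(length(eye$vd) == N_SECTORS)
  lat <- match.arg(eye$eye %||% "right", c("right", "left"))
  tsign <- if (lat == "right") 1 else -1

  nx <- round(cfg$width_mm / cfg$pixel_scale)
  ny <- round(cfg$height_mm / cfg$pixel_scale)
  cx <- if (lat == "right") cfg$disc_margin_mm else cfg$width_mm - cfg$disc_margin_mm
  cy <- cfg$height_mm / 2

  fa <- eye$fovea_angle * pi / 180
  fx <- cx + tsign * eye$fovea_distance * cos(fa)
  fy <- cy - eye$fovea_distance * sin(fa)
  pad <- cfg$fovea_radius_mm
  if (fx < pad || fx > cfg$width_mm - pad || fy < pad || fy > cfg$height_mm - pad)
    stop("canvas too small to contain the fovea landmark", call. = FALSE)

  g <- pixel_grid(nx, ny, cfg$pixel_scale)
  dx <- g$x - cx
  dy <- g$y - cy
  # normalized right-eye frame: temporal +x, superior +y
  xn <- tsign * dx
  yn <- -dy
  r <- sqrt(xn^2 + yn^2)
  theta <- atan2(yn, xn) %% (2 * pi)

  # disc ellipse
  a <- sqrt(eye$disc_area * eye$disc_ratio / pi)
  b <- sqrt(eye$disc_area / (eye$disc_ratio * pi))
  phi <- eye$disc_orientation * pi / 180
  u <- xn * cos(phi) + yn * sin(phi)
  v <- -xn * sin(phi) + yn * cos(phi)
  disc_mask <- (u / a)^2 + (v / b)^2 <= 1
  # disc rim radius along each pixel's direction
  r_rim <- a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)

  # vessels: one radial spoke per sector, width = caliber_per_unit * density,
  # constant through the annulus and tapering beyond it
  w <- cfg$caliber_per_unit * eye$vd
  centers <- sector_center_angles()
  r2 <- cfg$annulus_radii[2]
  taper <- ifelse(r > r2, (r2 / pmax(r, 1e-9))^1.5, 1)
  vessel_mask <- matrix(FALSE, ny, nx)
  sec <- angle_to_sector(theta)
  for (off in -1:1) {
    s_off <- ((sec - 1L + off) %% N_SECTORS) + 1L
    d_perp <- r * abs(sin(theta - centers[s_off]))
    vessel_mask <- vessel_mask |
      (d_perp <= w[s_off] * taper / 2 & r >= r_rim + 0.02 &
         r <= cfg$vessel_extent_mm)
  }

  fovea_mask <- (g$x - fx)^2 + (g$y - fy)^2 <= cfg$fovea_radius_mm^2

  px <- matrix(cfg$background, ny, nx)
  px[disc_mask] <- cfg$disc_gray
  px[fovea_mask] <- cfg$fovea_gray
  px[vessel_mask] <- cfg$vessel_gray

  structure(list(pixels = px, pixel_scale = cfg$pixel_scale,
                 disc_center = c(x = cx, y = cy),
                 fovea_center = c(x = fx, y = fy),
                 laterality = lat,
                 vessel_mask = vessel_mask, disc_mask = disc_mask,
                 config = cfg),
            class = "enface_image")
}

#' Write / read an en-face image as PNG with a JSON sidecar
#'
#' The sidecar records the pixel scale, landmark ground truth, laterality
#' and the density-to-caliber calibration so that extracted area-fraction
#' densities can be converted back to the cohort density scale.
#'
#' @param img an `enface_image`.
#' @param png_path,meta_path output paths; `meta_path` defaults to the PNG
#'   path with a `.json` extension.
#' @param write_masks if `TRUE`, ground-truth vessel and disc masks are
#'   written next to the image (suffixes `_vessels.png`, `_disc.png`).
#' @return `read_enface` returns an `enface_image` (without masks unless
#'   present on disk).
#' @export
write_enface <- function(img, png_path, meta_path = NULL, write_masks = FALSE) {
  meta_path <- meta_path %||% sub("\\.png$", ".json", png_path)
  png::writePNG(img$pixels, png_path)
  meta <- list(pixel_scale = img$pixel_scale,
               disc_center = as.list(img$disc_center),
               fovea_center = as.list(img$fovea_center),
               laterality = img$laterality,
               caliber_per_unit = img$config$caliber_per_unit,
               annulus_radii = img$config$annulus_radii)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  if (write_masks) {
    png::writePNG(img$vessel_mask * 1, sub("\\.png$", "_vessels.png", png_path))
    png::writePNG(img$disc_mask * 1, sub("\\.png$", "_disc.png", png_path))
  }
  invisible(png_path)
}

#' @rdname write_enface
#' @export
read_enface <- function(png_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.png$", ".json", png_path)
  px <- png::readPNG(png_path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- image_config(pixel_scale = meta$pixel_scale,
                      caliber_per_unit = meta$caliber_per_unit %||% 0.008,
                      annulus_radii = as.numeric(meta$annulus_radii %||% c(1.64, 1.82)))
  structure(list(pixels = px, pixel_scale = meta$pixel_scale,
                 disc_center = unlist(meta$disc_center),
                 fovea_center = unlist(meta$fovea_center),
                 laterality = meta$laterality %||% "right",
                 vessel_mask = NULL, disc_mask = NULL, config = cfg),
            class = "enface_image")
}
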