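#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

N_SECTORS <- 256L

# Quadrant index blocks in the normalized right-eye TSNIT-style convention:
# sector 0 starts at the temporal horizontal meridian and indices proceed
# superiorly, so each quadrant is a contiguous block of 64 sectors.
QUADRANTS <- list(
  temporal = 1:64,
  superior = 65:128,
  nasal    = 129:192,
  inferior = 193:256
)

ETDRS_SECTORS <- c(
  "fovea",
  "inner_superior", "inner_nasal", "inner_inferior", "inner_temporal",
  "outer_superior", "outer_nasal", "outer_inferior", "outer_temporal"
)

MACULAR_LAYERS <- c("mrnfl", "mgcl", "mipl")

#' Sector center angles
#'
#' Angles (radians) of the 256 sector centers, measured from the temporal
#' horizontal meridian toward the superior pole in the normalized right-eye
#' frame.
#' @return numeric vector of length 256.
#' @keywords internal
sector_center_angles <- function() {
  (seq_len(N_SECTORS) - 0.5) * (2 * pi / N_SECTORS)
}

# Map an angle (radians, temporal->superior convention) to a sector index
# in 1..256.
angle_to_sector <- function(theta) {
  theta <- theta %% (2 * pi)
  pmin(N_SECTORS, floor(theta / (2 * pi / N_SECTORS)) + 1L)
}

#' Mirror a sector profile between left- and right-eye orientation
#'
#' Mirroring about the vertical axis maps an angle theta to 180 - theta
#' (degrees); at the 256-sector resolution this is an index reversal around
#' the superior/inferior axis.  The operation is an involution.
#'
#' @param values numeric vector of length 256.
#' @return numeric vector of length 256 in the mirrored orientation.
#' @export
mirror_profile <- function(values) {
  stopifnot(length(values) == N_SECTORS)
  s <- 0:(N_SECTORS - 1)
  values[((127L - s) %% N_SECTORS) + 1L]
}

sector_cols <- function(prefix) sprintf("%s_%03d", prefix, 0:(N_SECTORS - 1))

macular_cols <- function() {
  as.vector(t(outer(MACULAR_LAYERS, ETDRS_SECTORS, paste, sep = "_")))
}

profile_matrix <- function(cohort, prefix) {
  cols <- sector_cols(prefix)
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0)
    stop("cohort is missing sector columns: ", missing[1], " ...")
  as.matrix(cohort[, cols, drop = FALSE])
}

# Draws n_eye standard-normal deviates with correlation `rho` between eyes
# of the same subject: z = sqrt(rho) z_subject + sqrt(1-rho) z_eye.
rho_normal <- function(subject_index, n_subjects, rho) {
  zs <- stats::rnorm(n_subjects)
  ze <- stats::rnorm(length(subject_index))
  sqrt(rho) * zs[subject_index] + sqrt(1 - rho) * ze
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
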