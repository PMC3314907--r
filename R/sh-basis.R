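# Real solid spherical harmonics up to 3rd order and weighted least-squares
# fitting of scalar fields on a voxel grid. Gradient-coil perturbation
# fields are conventionally expanded in regular solid harmonics (harmonic
# polynomials in x, y, z), which can be evaluated at any radius; surface
# harmonics on a fixed sphere cannot.

#' Reference frame for spherical-harmonic evaluation
#'
#' Solid harmonics are evaluated in scanner (world) coordinates. Coordinates
#' are shifted by `origin_mm` (the presumed isocentre) and divided by the
#' characteristic radius `R_ref_mm` before evaluating the polynomial basis,
#' which keeps the design matrix well conditioned across orders.
#'
#' @param origin_mm world-space origin (default the affine's origin, 0,0,0).
#' @param R_ref_mm characteristic radius in mm (default 150, roughly the
#'   bore radius of a clinical gradient coil).
#' @return list of class `sh_frame`.
#' @export
sh_frame <- function(origin_mm = c(0, 0, 0), R_ref_mm = 150) {
  stopifnot(length(origin_mm) == 3, R_ref_mm > 0)
  structure(list(origin_mm = as.numeric(origin_mm),
                 R_ref_mm = as.numeric(R_ref_mm)),
            class = "sh_frame")
}

frames_equal <- function(a, b, tol = 1e-9) {
  max(abs(a$origin_mm - b$origin_mm)) <= tol &&
    abs(a$R_ref_mm - b$R_ref_mm) <= tol
}

# (l, m) ordering of the basis columns: l ascending, m = -l..l
sh_lm_table <- function(order) {
  l <- rep(0:order, times = 2 * (0:order) + 1)
  m <- unlist(lapply(0:order, function(ll) seq(-ll, ll)))
  data.frame(l = l, m = m)
}

#' Design matrix of real solid spherical harmonics
#'
#' Columns are the regular real solid harmonics `r^l Y_lm` (harmonic
#' polynomials in x, y, z), unnormalized, ordered with `l` ascending and
#' `m = -l..l`; column 1 is the constant. Orders up to 3 are supported:
#' `(order+1)^2` columns (16 at order 3).
#'
#' @param points N x 3 matrix of world-mm coordinates.
#' @param order maximum harmonic order (0 to 3).
#' @param frame an [sh_frame] giving origin and scaling radius.
#' @return N x (order+1)^2 numeric matrix.
#' @export
sh_design_matrix <- function(points, order = 3, frame = sh_frame()) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)),
            order >= 0, order == round(order))
  if (order > 3) stop("spherical-harmonic orders above 3 are not supported")
  x <- (points[, 1] - frame$origin_mm[1]) / frame$R_ref_mm
  y <- (points[, 2] - frame$origin_mm[2]) / frame$R_ref_mm
  z <- (points[, 3] - frame$origin_mm[3]) / frame$R_ref_mm
  n <- length(x)
  cols <- list(rep(1, n))
  if (order >= 1) cols <- c(cols, list(y, z, x))
  if (order >= 2) {
    r2 <- x^2 + y^2 + z^2
    cols <- c(cols, list(x * y, y * z, 3 * z^2 - r2, x * z, x^2 - y^2))
  }
  if (order >= 3) {
    r2 <- x^2 + y^2 + z^2
    cols <- c(cols, list(
      y * (3 * x^2 - y^2),
      x * y * z,
      y * (5 * z^2 - r2),
      z * (5 * z^2 - 3 * r2),
      x * (5 * z^2 - r2),
      z * (x^2 - y^2),
      x * (x^2 - 3 * y^2)))
  }
  out <- do.call(cbind, cols)
  lm <- sh_lm_table(order)
  colnames(out) <- sprintf("l%dm%+d", lm$l, lm$m)
  out
}

#' Spherical-harmonic coefficient set
#'
#' @param coefficients numeric vector of length `(order+1)^2`.
#' @param order harmonic order.
#' @param frame an [sh_frame].
#' @return object of class `sh_coefficients`.
#' @export
sh_coefficients <- function(coefficients, order = 3, frame = sh_frame()) {
  stopifnot(length(coefficients) == (order + 1)^2, order >= 0)
  structure(list(order = order, coefficients = as.numeric(coefficients),
                 frame = frame),
            class = "sh_coefficients")
}

#' Weighted least-squares fit of a sampled scalar field
#'
#' Minimizes `sum(w_i * (values_i - design_i %*% c)^2)`. Exact on fields in
#' the column space when all weights are positive; zero-weight samples do
#' not influence the solution.
#'
#' @param design N x K design matrix (e.g. from [sh_design_matrix]).
#' @param values N observed values.
#' @param weights N non-negative weights (default all 1).
#' @return numeric coefficient vector of length K, with attribute
#'   `residual_var` (weighted residual variance).
#' @export
wls_fit <- function(design, values, weights = NULL) {
  design <- as.matrix(design)
  n <- nrow(design); k <- ncol(design)
  if (n < k) stop("fewer samples than coefficients")
  w <- weights %||% rep(1, n)
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("all weights are zero")
  sw <- sqrt(w)
  qrd <- qr(design * sw)
  if (qrd$rank < k) {
    dropped <- setdiff(seq_len(k), qrd$pivot[seq_len(qrd$rank)])
    nm <- colnames(design) %||% as.character(seq_len(k))
    stop(sprintf("effective rank %d < %d after weighting; deficient columns: %s",
                 qrd$rank, k, paste(nm[dropped], collapse = ", ")))
  }
  coef <- qr.coef(qrd, values * sw)
  resid <- values - design %*% coef
  structure(as.numeric(coef),
            residual_var = sum(w * resid^2) / max(sum(w > 0) - k, 1))
}

#' Evaluate a spherical-harmonic field at points
#'
#' @param coeffs an [sh_coefficients] object.
#' @param points N x 3 matrix of world-mm coordinates.
#' @return numeric vector of N field values.
#' @export
evaluate_field <- function(coeffs, points) {
  stopifnot(inherits(coeffs, "sh_coefficients"))
  as.numeric(sh_design_matrix(points, coeffs$order, coeffs$frame) %*%
               coeffs$coefficients)
}
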