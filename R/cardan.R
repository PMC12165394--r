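#' Cardan XYZ decomposition of a rotation-matrix series
#'
#' Decomposes each 3x3 rotation as `Rx(alpha) %*% Ry(beta) %*% Rz(gamma)`,
#' the XYZ Cardan sequence of the standardized joint coordinate system. The
#' first angle (`alpha`) is the flexion-extension angle used for range-of-
#' motion metrics. Angles are continuity-unwrapped across frames and frames
#' near gimbal lock (|beta| > 89 deg) are flagged.
#'
#' @param rot A T x 9 numeric matrix of row-major rotation components, or a
#'   list of 3x3 matrices.
#' @param tol Orthonormality tolerance.
#'
#' @return A tibble with columns `alpha`, `beta`, `gamma` (degrees) and
#'   `gimbal` (logical).
#' @export
#' @examples
#' R <- compose_cardan_xyz(30, 0, 0)
#' cardan_xyz_angles(matrix(as.vector(t(R)), 1, 9))
cardan_xyz_angles <- function(rot, tol = 1e-6) {
  if (is.list(rot) && !is.data.frame(rot)) {
    rot <- t(vapply(rot, function(M) as.vector(t(M)), numeric(9)))
  }
  rot <- as.matrix(rot)
  if (ncol(rot) != 9) {
    abort("Rotation input must have 9 components per frame (row-major).",
          class = "pdgait_format_error")
  }
  chk <- rotation_checks(rot)
  bad <- which(chk$err > tol | chk$det < 0)
  if (length(bad)) {
    abort(sprintf("Frame %d is not a proper rotation matrix.", bad[1]),
          class = "pdgait_validation_error")
  }
  # row-major layout: r11 r12 r13 r21 r22 r23 r31 r32 r33
  b <- asin(pmax(-1, pmin(1, rot[, 3])))
  a <- atan2(-rot[, 6], rot[, 9])
  g <- atan2(-rot[, 2], rot[, 1])
  a <- unwrap_angle(a)
  g <- unwrap_angle(g)
  tibble::tibble(
    alpha = a * 180 / pi,
    beta = b * 180 / pi,
    gamma = g * 180 / pi,
    gimbal = abs(b) * 180 / pi > 89
  )
}

# remove 2*pi jumps from a radian series
unwrap_angle <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  jumps <- round(d / (2 * pi))
  x - c(0, cumsum(jumps)) * 2 * pi
}

#' Compose a rotation matrix from Cardan XYZ angles
#'
#' Inverse of [cardan_xyz_angles()]: builds
#' `Rx(alpha) %*% Ry(beta) %*% Rz(gamma)` from angles in degrees.
#'
#' @param alpha,beta,gamma Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
compose_cardan_xyz <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

# vectorized Rx(alpha) Ry(beta) Rz(gamma) with fixed beta/gamma, returning a
# T x 9 row-major matrix (used by the walking simulator)
cardan_xyz_series <- function(alpha_deg, beta_deg, gamma_deg) {
  a <- alpha_deg * pi / 180
  b <- rep(beta_deg * pi / 180, length.out = length(a))
  g <- rep(gamma_deg * pi / 180, length.out = length(a))
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  cbind(
    cb * cg, -cb * sg, sb,
    ca * sg + sa * sb * cg, ca * cg - sa * sb * sg, -sa * cb,
    sa * sg - ca * sb * cg, sa * cg + ca * sb * sg, ca * cb
  )
}

#' Bilateral symmetry angle
#'
#' Maps a left/right value pair to a percentage asymmetry: 0% for perfect
#' symmetry, +/-50% when one side is zero. Computed as
#' `(45 - atan2(left, right) in degrees) / 90 * 100`, with a 180-degree
#' adjustment when the raw deviation exceeds 90 degrees. The tabulated
#' convention is the magnitude; set `signed = TRUE` for the signed value
#' (positive when the right side dominates).
#'
#' @param x_left,x_right Non-negative side values (e.g., shoulder ROM).
#' @param signed Return the signed value instead of the magnitude.
#'
#' @return Symmetry angle in percent (vectorized).
#' @export
#' @examples
#' symmetry_angle(30, 30) # 0
#' symmetry_angle(30, 40) # 9.03...
symmetry_angle <- function(x_left, x_right, signed = FALSE) {
  if (any(x_left == 0 & x_right == 0)) {
    abort("Symmetry angle is undefined when both sides are zero.",
          class = "pdgait_precondition_error")
  }
  theta <- atan2(x_left, x_right) * 180 / pi
  d <- 45 - theta
  d <- ifelse(d > 90, d - 180, ifelse(d < -90, d + 180, d))
  sa <- d / 90 * 100
  if (signed) sa else abs(sa)
}

#' Impaired-side selection rule
#'
#' For side-specific metrics (toe clearance, hip ROM) only the clinically
#' impaired side enters the analysis; participants with bilateral or no
#' impairment contribute the average across sides.
#'
#' @param left,right Side values.
#' @param impaired_side One of `"left"`, `"right"`, `"bilateral"`, `"none"`.
#'
#' @return Scalar value for analysis.
#' @export
impaired_side_value <- function(left, right,
                                impaired_side = c("none", "left", "right", "bilateral")) {
  impaired_side <- match.arg(impaired_side)
  pick <- switch(impaired_side,
                 left = left,
                 right = right,
                 bilateral = ,
                 none = (left + right) / 2)
  if (is.null(pick) || !is.finite(pick)) {
    abort(sprintf("Missing side value for impaired-side rule '%s'.", impaired_side),
          class = "pdgait_precondition_error")
  }
  pick
}
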