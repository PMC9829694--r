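#' Affine world-coordinate transforms
#'
#' An `affine_transform` is a 4x4 homogeneous matrix mapping world coordinates
#' (mm) to world coordinates. By the pull-back convention used throughout the
#' package, a transform passed to [resample_volume()] maps points in the
#' *reference* (output) space into the *source* volume's space.
#'
#' @param matrix numeric 4x4 matrix; last row must be `(0, 0, 0, 1)` and the
#'   upper-left 3x3 block must be invertible.
#' @return An object of class `affine_transform`.
#' @seealso [compose_affine()], [invert_affine()], [affine_from_params()]
#' @export
affine_transform <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || !all(dim(matrix) == c(4L, 4L)))
    stop("affine matrix must be numeric 4x4")
  if (any(abs(matrix[4L, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last row of an affine matrix must be (0, 0, 0, 1)")
  d <- det(matrix[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("affine matrix is singular")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @export
#' @rdname affine_transform
identity_affine <- function() affine_transform(diag(4))

#' Compose two affine transforms
#'
#' `compose_affine(outer, inner)` returns the transform whose application
#' equals applying `inner` first, then `outer`.
#'
#' @param outer,inner `affine_transform` objects.
#' @return An `affine_transform`.
#' @export
compose_affine <- function(outer, inner) {
  stopifnot(inherits(outer, "affine_transform"), inherits(inner, "affine_transform"))
  affine_transform(outer$matrix %*% inner$matrix)
}

#' Invert an affine transform
#' @param transform an `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  affine_transform(solve(transform$matrix))
}

#' Apply an affine transform to points
#'
#' @param transform an `affine_transform`.
#' @param points numeric n x 3 matrix (or length-3 vector) of world
#'   coordinates in mm.
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_affine <- function(transform, points) {
  stopifnot(inherits(transform, "affine_transform"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  stopifnot(ncol(points) == 3L)
  h <- cbind(points, 1)
  out <- h %*% t(transform$matrix)
  out[, 1:3, drop = FALSE]
}

# Rotation about x, y, z (radians), applied as Rx %*% Ry %*% Rz
# (written out, as this sits under the registration inner loop).
rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  matrix(c(cy * cz, sx * sy * cz + cx * sz, -cx * sy * cz + sx * sz,
           -cy * sz, -sx * sy * sz + cx * cz, cx * sy * sz + sx * cz,
           sy, -sx * cy, cx * cy),
         nrow = 3L)
}

#' Build an affine transform from physical parameters
#'
#' Parameterization used by the registration optimizer: translation in mm,
#' rotation as Euler angles in radians, per-axis log-scales and shear
#' coefficients, applied about a fixed centre of rotation so that rotation
#' and translation are decorrelated.
#'
#' The map is `T(center) T(translation) R Shear Scale T(-center)`.
#'
#' @param translation length-3, mm.
#' @param rotation length-3 Euler angles (radians) about x, y, z.
#' @param log_scale length-3 per-axis log scale factors.
#' @param shear length-3 (xy, xz, yz) shear coefficients.
#' @param center length-3 centre of rotation in world mm.
#' @return An `affine_transform`.
#' @export
affine_from_params <- function(translation = c(0, 0, 0),
                               rotation = c(0, 0, 0),
                               log_scale = c(0, 0, 0),
                               shear = c(0, 0, 0),
                               center = c(0, 0, 0)) {
  R <- rotation_matrix(rotation[1], rotation[2], rotation[3])
  Sh <- diag(3)
  Sh[1, 2] <- shear[1]; Sh[1, 3] <- shear[2]; Sh[2, 3] <- shear[3]
  S <- diag(exp(log_scale))
  A <- R %*% Sh %*% S
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- translation + center - A %*% center
  affine_transform(m)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("Affine world transform (mm):\n")
  print(round(x$matrix, 6))
  invisible(x)
}
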