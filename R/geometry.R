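# Elementary rotation and frame utilities. All rotations are right-handed,
# active, and expressed as 3x3 matrices acting on column vectors.

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Intrinsic z-y-x rotation
#'
#' Composes the joint rotation used throughout the package: an intrinsic
#' rotation first about z, then the new y, then the new x axis.
#'
#' @param az,ay,ax angles in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_zyx <- function(az, ay, ax) {
  rot_z(az) %*% rot_y(ay) %*% rot_x(ax)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

is_orthonormal <- function(M, tol = 1e-9) {
  all(abs(crossprod(M) - diag(3)) < tol) && det(M) > 0
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
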