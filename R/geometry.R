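# Rotation and frame utilities.
#
# Global frame convention used throughout the package (documented in the
# methods vignette and pinned by tests):
#   +X patient-left, +Y anterior, +Z cranial (right-handed).
#   Coronal plane = XZ (normal +Y); sagittal plane = YZ (normal +X).
# Rotations are 3x3 orthonormal matrices; incremental rotations are
# parametrized by rotation vectors (axis * angle, radians) composed
# multiplicatively on the left: R(q) = exp([q]x) R0.

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v numeric length-3 vector.
#' @return 3x3 matrix `S` with `S %*% w == v x w`.
#' @keywords internal
skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rotation matrix from a rotation vector (Rodrigues formula)
#' @param q rotation vector (axis times angle, radians).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_exp <- function(q) {
  th2 <- sum(q * q)
  S <- skew(q)
  if (th2 < 1e-16) {
    # second-order Taylor keeps orthonormality to machine precision here
    return(diag(3) + S + 0.5 * (S %*% S))
  }
  th <- sqrt(th2)
  diag(3) + (sin(th) / th) * S + ((1 - cos(th)) / th2) * (S %*% S)
}

#' Rotation vector from a rotation matrix (matrix logarithm on SO(3))
#' @param R 3x3 rotation matrix.
#' @return rotation vector, angle between 0 and pi.
#' @keywords internal
rot_log <- function(R) {
  c_th <- (sum(diag(R)) - 1) / 2
  c_th <- min(1, max(-1, c_th))
  th <- acos(c_th)
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  if (th < 1e-7) {
    return(w * (1 + th * th / 6))   # w = sin(th)*axis ; series for th/sin(th)
  }
  if (th > pi - 1e-5) {
    # near pi the vee-part is ill-conditioned; use the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    i <- which.max(ax)
    if (R[3, 2] - R[2, 3] < 0 && i == 1) ax[1] <- -ax[1]
    s <- sign(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
    s[s == 0] <- 1
    ax <- abs(ax) * s
    n <- sqrt(sum(ax^2))
    if (n < 1e-12) return(c(th, 0, 0))
    return(ax / n * th)
  }
  w / sin(th) * th
}

#' Left Jacobian of SO(3)
#'
#' Satisfies `d/dt exp(skew(q + t*e_k)) = skew(Jl(q) e_k) exp(skew(q))` at
#' t = 0, so its columns give the spatial derivative of the exponential map.
#' @keywords internal
so3_jacl <- function(q) {
  th2 <- sum(q * q)
  S <- skew(q)
  if (th2 < 1e-16) return(diag(3) + 0.5 * S + (S %*% S) / 6)
  th <- sqrt(th2)
  diag(3) + ((1 - cos(th)) / th2) * S + ((th - sin(th)) / (th2 * th)) * (S %*% S)
}

#' Inverse left Jacobian of SO(3)
#'
#' Maps a left (spatial) angular perturbation w of `R = exp(skew(phi))` to
#' the corresponding rotation-vector perturbation `dphi = Jl_inv(phi) w`.
#' @keywords internal
so3_jacl_inv <- function(q) {
  th2 <- sum(q * q)
  S <- skew(q)
  if (th2 < 1e-16) return(diag(3) - 0.5 * S + (S %*% S) / 12)
  th <- sqrt(th2)
  diag(3) - 0.5 * S + (1 / th2 - (1 + cos(th)) / (2 * th * sin(th))) * (S %*% S)
}

#' Elementary rotations about the global axes
#' @param a angle in radians.
#' @keywords internal
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
#' @rdname rot_x
#' @keywords internal
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
#' @rdname rot_x
#' @keywords internal
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Rotation taking unit vector a onto unit vector b by the minimal arc
#' @keywords internal
rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    return(rot_exp(pi * ax / sqrt(sum(ax^2))))
  }
  S <- skew(v)
  diag(3) + S + (S %*% S) / (1 + c_)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two 2D directions, unsigned, in degrees
#' @keywords internal
angle_between_2d <- function(u, v) {
  a <- atan2(u[2], u[1]) - atan2(v[2], v[1])
  a <- atan2(sin(a), cos(a))
  abs(rad2deg(a))
}

#' Signed angle from v to u in 2D (counter-clockwise positive), degrees
#' @keywords internal
angle_signed_2d <- function(u, v) {
  a <- atan2(u[2], u[1]) - atan2(v[2], v[1])
  rad2deg(atan2(sin(a), cos(a)))
}

#' Rigid least-squares registration (Kabsch)
#'
#' Finds rotation R and translation t minimizing sum |R x_i + t - y_i|^2.
#' @param X,Y n x 3 matrices of matched points.
#' @return list with `R` (3x3) and `t` (length 3).
#' @keywords internal
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = cy - as.vector(R %*% cx))
}
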