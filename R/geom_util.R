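# Small 3D rotation utilities used throughout the multibody code.
# Global frame convention: right-handed, X anterior, Y to the patient's
# left, Z cephalad; coronal plane = YZ, sagittal = XZ, transverse = XY.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# Rodrigues formula: rotation vector (radians) -> rotation matrix.
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v * v))
  if (th < 1e-12) {
    K <- skew3(v)
    return(diag(3) + K + 0.5 * K %*% K)
  }
  K <- skew3(v / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation matrix -> rotation vector (radians), |v| in [0, pi].
matrix_to_rotvec <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  c_ <- max(-1, min(1, c_))
  th <- acos(c_)
  if (th < 1e-8) {
    return(0.5 * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  }
  if (th > pi - 1e-6) {
    # near pi: extract axis from the symmetric part
    A <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(A), 0))
    i <- which.max(ax)
    ax <- A[, i] / ax[i]
    ax <- ax / sqrt(sum(ax^2))
    return(th * ax)
  }
  (th / (2 * sin(th))) * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
}

vnorm <- function(v) sqrt(sum(v * v))
normalize <- function(v) v / vnorm(v)

# Angle (deg, in [0, 180)) between two lines given direction vectors,
# optionally after projection onto a coordinate plane.
line_angle_deg <- function(u, v) {
  cu <- vnorm(u); cv <- vnorm(v)
  if (cu < 1e-12 || cv < 1e-12) return(0)
  d <- abs(sum(u * v)) / (cu * cv)
  rad2deg(acos(max(-1, min(1, d))))
}
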