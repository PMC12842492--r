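#' @importFrom stats rnorm runif sd setNames optim
NULL

# ---- rotation helpers -------------------------------------------------------

# unit quaternion (w, x, y, z) -> 3x3 rotation matrix
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# rotation vector (axis * angle, radians) -> quaternion
rotvec_to_quat <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(c(1, 0, 0, 0))
  c(cos(theta / 2), sin(theta / 2) * v / theta)
}

random_unit_quat <- function() {
  # Shoemake's uniform quaternion sampling
  u <- runif(3)
  c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
}

# Rodrigues rotation of points (n x 3) about unit axis through origin
rotate_about_axis <- function(pts, axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), nrow = 3, byrow = TRUE)
  R <- diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
  pts %*% t(R)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# ---- Kabsch superposition ---------------------------------------------------

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Translates both point sets to their centroids, finds the optimal proper
#' rotation by the Kabsch (SVD) algorithm, and returns the root-mean-square
#' deviation in Angstroms. Reflections are excluded, so chirality is
#' preserved.
#'
#' @param P,Q Numeric matrices of matched coordinates, one row per atom,
#'   three columns. Must have equal dimensions.
#' @return A single non-negative number, the RMSD in Angstroms.
#' @examples
#' P <- matrix(c(0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
#' Q <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
#' kabsch_rmsd(P, Q) # 0.5
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) {
    stop("kabsch_rmsd(): coordinate sets differ in size (",
         nrow(P), " vs ", nrow(Q), " points)")
  }
  if (ncol(P) != 3) stop("kabsch_rmsd(): coordinates must be n x 3")
  n <- nrow(P)
  if (n == 0) stop("kabsch_rmsd(): empty coordinate sets")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Pr <- Pc %*% t(R)
  sqrt(sum((Pr - Qc)^2) / n)
}

apply_rigid <- function(pts, R, t) sweep(as.matrix(pts) %*% t(R), 2, t, `+`)

random_rotation_matrix <- function() quat_to_mat(random_unit_quat())
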