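# Low-level vector geometry shared by the builders, the docking moves and the
# interaction detectors. All angles are in degrees at the interface and
# radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vlen <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vlen(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Angle at `b` formed by points `a`-`b`-`c`, in degrees.
#' @noRd
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed torsion a-b-c-d in degrees, IUPAC convention.
#' @noRd
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

#' Place a fourth atom from three reference positions and internal
#' coordinates (natural extension reference frame construction).
#'
#' Returns the position `d` such that |d - c| = bond, angle(b, c, d) = angle
#' and torsion(a, b, c, d) = torsion.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  chi <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi), bond * sin(th) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix about an arbitrary axis (Rodrigues), angle in degrees.
#' @noRd
rotation_matrix <- function(axis, angle) {
  u <- unitv(axis)
  th <- deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Uniform random rotation matrix (quaternion method); consumes 4 normal
#' deviates from the active RNG stream.
#' @noRd
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vlen(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate the rows of `xyz` (n x 3) about the axis through `origin`.
#' @noRd
rotate_about <- function(xyz, origin, axis, angle) {
  R <- rotation_matrix(axis, angle)
  sweep(sweep(xyz, 2, origin, "-") %*% t(R), 2, origin, "+")
}

#' Least-squares superposition (Kabsch). Returns the rotation matrix and
#' translation mapping `mobile` onto `fixed`; both are n x 3 matrices of
#' paired points.
#' @noRd
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm, "-")
  Q <- sweep(fixed, 2, cf, "-")
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, center_mobile = cm, center_fixed = cf)
}

apply_kabsch <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mobile, "-") %*% t(fit$R), 2, fit$center_fixed, "+")
}

#' Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
#' @noRd
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Pairwise squared distances between the rows of two n x 3 matrices.
#' @noRd
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
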