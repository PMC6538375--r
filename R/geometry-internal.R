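# Low-level 3D geometry: vector helpers, internal-coordinate atom placement
# (NeRF), dihedrals, rotations and the Kabsch superposition core. All
# functions here are internal; coordinates are plain numeric length-3 vectors
# or n x 3 matrices in Angstrom.

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate (zero-length) vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.deg2rad <- function(x) x * pi / 180

.rad2deg <- function(x) x * 180 / pi

# Place atom D given positions of A, B, C, the C-D bond length, the B-C-D
# angle (degrees) and the A-B-C-D dihedral (degrees). Standard NeRF
# construction: the returned point has exactly the requested internal
# coordinates.
.placeAtom <- function(a, b, c, len, angle, dihedral) {
  th <- .deg2rad(angle)
  ch <- .deg2rad(dihedral)
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- len * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + cbind(bc, m, n) %*% d2
}

# Dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180], IUPAC sign
# convention (clockwise positive looking from p2 to p3).
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -.rad2deg(atan2(y, x))
}

.angleDeg <- function(p1, p2, p3) {
  v1 <- .vunit(p1 - p2)
  v2 <- .vunit(p3 - p2)
  .rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

# Rotation matrix from z-y-z Euler angles (degrees), active convention:
# R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma).
.eulerZYZ <- function(alpha, beta, gamma) {
  a <- .deg2rad(alpha); b <- .deg2rad(beta); g <- .deg2rad(gamma)
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3L, 3L)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3L, 3L)
  rz(a) %*% ry(b) %*% rz(g)
}

# Rotation about a unit axis by angle in degrees (Rodrigues).
.axisRotation <- function(axis, angle) {
  u <- .vunit(axis)
  t <- .deg2rad(angle)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# Kabsch: optimal proper rotation R and translation t such that
# mobile %*% R + t best fits reference in least squares. Matrices are n x 3.
.kabschCore <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), ncol(mobile) == 3L)
  if (nrow(mobile) < 3L) stop("need at least 3 paired atoms for superposition")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(reference, 2L, cr)
  H <- crossprod(X, Y)
  sv <- svd(H)
  # guard against reflections and degenerate (collinear) selections
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    stop("degenerate atom selection: points are collinear or coincident")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  t <- cr - as.numeric(cm %*% R)
  list(rotation = R, translation = t, rmsd = rmsd)
}
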