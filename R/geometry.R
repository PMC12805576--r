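## Vectorised internal-coordinate geometry. Trajectory coordinates are kept
## as an array [frame, bead, xyz]; the helpers below operate column-wise
## across frames so per-frame R loops are avoided.

vnorm <- function(m) sqrt(rowSums(m * m))

## m-row cross product of two n x 3 matrices
vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Distances/angles/dihedrals per frame from coordinate slabs (n x 3 each).
frame_distances <- function(a, b) vnorm(b - a)

frame_angles <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- rowSums(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

## IUPAC torsion, right-handed, wrapped to (-180, 180].
frame_dihedrals <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  phi <- rad2deg(atan2(y, x))
  wrap_angle(phi)
}

## wrap degrees to (-180, 180]
wrap_angle <- function(phi) {
  w <- phi - 360 * floor((phi + 180) / 360)
  w[w == -180] <- 180
  w
}

## NeRF bead placement, vectorised across frames: place point D given
## A, B, C slabs (n x 3), bond |CD|, angle BCD (deg) and dihedral ABCD
## (deg), each a length-n vector.
place_nerf <- function(a, b, c, r, theta, phi) {
  th <- deg2rad(180 - theta)   # supplement: local x points away from B
  ph <- deg2rad(phi)
  d2 <- cbind(r * cos(th), r * cos(ph) * sin(th), r * sin(ph) * sin(th))
  bc <- c - b; bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc); n <- n / vnorm(n)
  m <- vcross(n, bc)
  ## rotate local coords into lab frame: columns bc, m, n
  c + cbind(
    d2[, 1] * bc[, 1] + d2[, 2] * m[, 1] + d2[, 3] * n[, 1],
    d2[, 1] * bc[, 2] + d2[, 2] * m[, 2] + d2[, 3] * n[, 2],
    d2[, 1] * bc[, 3] + d2[, 2] * m[, 3] + d2[, 3] * n[, 3])
}

## Kabsch least-squares superposition of x onto ref (both n x 3).
## Returns the rotated+translated copy of x.
kabsch_superpose <- function(x, ref) {
  cx <- colMeans(x); cr <- colMeans(ref)
  x0 <- sweep(x, 2, cx); r0 <- sweep(ref, 2, cr)
  s <- svd(crossprod(x0, r0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(x0 %*% t(rot), 2, cr, "+")
}

## random rotation matrix (uniform via QR of Gaussian)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
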