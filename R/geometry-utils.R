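# Small 3D geometry helpers shared by the fragment grammar, the symmetry
# detector and the shape descriptors.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Deterministic unit vector perpendicular to v.
.perp <- function(v) {
  v <- .unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(ref - sum(ref * v) * v)
}

# Rotation matrix about `axis` by `angle` (radians), Rodrigues form.
.rotmat <- function(axis, angle) {
  a <- .unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Reflection through the plane with unit normal n (through the origin).
.reflmat <- function(n) {
  n <- .unit(n)
  diag(3) - 2 * tcrossprod(n)
}

# Rotation taking the +z axis onto direction d (deterministic).
.align_z_to <- function(d) {
  d <- .unit(d)
  z <- c(0, 0, 1)
  c_ <- sum(z * d)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(.rotmat(c(1, 0, 0), pi))
  .rotmat(c(z[2] * d[3] - z[3] * d[2],
            z[3] * d[1] - z[1] * d[3],
            z[1] * d[2] - z[2] * d[1]), acos(c_))
}

# Random rigid motion (proper rotation + translation), using the current RNG.
.random_rigid_motion <- function() {
  ax <- stats::rnorm(3)
  R <- .rotmat(ax, stats::runif(1, 0, 2 * pi))
  t <- stats::rnorm(3, sd = 3)
  list(R = R, t = t)
}

.apply_rigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2, -motion$t)
}

# Best proper rotation (Kabsch) and best improper orthogonal map superposing
# P onto Q (both n x 3, already centred; atoms transform as p -> O %*% p).
# Returns, for each parity, the optimal matrix and its max per-atom
# displacement.
.procrustes_residuals <- function(P, Q) {
  H <- crossprod(P, Q)           # P^T Q
  sv <- svd(H)
  s <- det(sv$v %*% t(sv$u))
  O_rot <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  O_imp <- sv$v %*% diag(c(1, 1, -s)) %*% t(sv$u)
  resid <- function(O) max(sqrt(rowSums((P %*% t(O) - Q)^2)))
  list(rot = list(O = O_rot, max_disp = resid(O_rot)),
       imp = list(O = O_imp, max_disp = resid(O_imp)))
}
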