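# Small 3D geometry kernel shared by all modules. Vectors are length-3
# numerics; point sets are n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle_deg`
#' degrees about the (not necessarily unit) axis `axis`.
#'
#' @param axis length-3 numeric axis direction.
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# NeRF atom placement: position D such that |C-D| = length_, angle(B,C,D) =
# angle_deg and dihedral(A,B,C,D) = dihedral_deg. Used for side-chain gamma
# candidates and toy-backbone construction.
place_atom <- function(a, b, c_, length_, angle_deg, dihedral_deg) {
  drop(place_atoms(a, b, c_, length_, angle_deg, dihedral_deg))
}

# Vectorized over dihedral_deg: returns length(dihedral_deg) x 3 matrix.
place_atoms <- function(a, b, c_, length_, angle_deg, dihedral_deg) {
  bc <- unitv(c_ - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  th <- deg2rad(angle_deg)
  ch <- deg2rad(dihedral_deg)
  d2 <- cbind(-length_ * cos(th),
              length_ * sin(th) * cos(ch),
              length_ * sin(th) * sin(ch))
  sweep(d2 %*% t(cbind(bc, m, n)), 2, c_, "+")
}

# Signed dihedral angle in degrees, IUPAC convention, range (-180, 180].
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * unitv(b2))
  rad2deg(atan2(y, x))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R (det +1) and translation t minimizing
#' ||R p_i + t - q_i||^2 over paired points.
#'
#' @param P mobile n x 3 matrix.
#' @param Q reference n x 3 matrix (same n).
#' @return list with `R` (3x3), `t` (length 3), `rmsd` (post-fit, Angstrom).
#' @keywords internal
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), nrow(P) == nrow(Q), ncol(P) == 3)
  if (nrow(P) < 3) stop("superposition needs at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate (collinear) selection: rotation undefined")
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_ <- cq - drop(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t_, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t_, rmsd = rmsd)
}

apply_rigid <- function(xyz, R, t_) {
  sweep(xyz %*% t(R), 2, t_, "+")
}

# All permutations of 1..n as a matrix (n! rows); n <= 6 in practice.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

hf_error <- function(msg, class = "helixforge_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
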