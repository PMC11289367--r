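#' Helical symmetry parameters
#'
#' Rise (Angstrom per subunit, > 0) and twist (degrees per subunit, signed;
#' negative means the 1-start helix is left-handed with subunit index
#' increasing along the +axis, the convention under which actin filaments are
#' reported near -167 degrees).
#'
#' @param rise axial translation per subunit, Angstrom (> 0).
#' @param twist rotation per subunit, degrees, in (-360, 360).
#' @return an object of class `HelicalSymmetry`.
#' @export
helical_symmetry <- function(rise, twist) {
  if (!is.finite(rise) || rise <= 0) hf_error("rise must be positive")
  if (!is.finite(twist) || abs(twist) >= 360)
    hf_error("twist must lie in (-360, 360)")
  structure(list(rise = rise, twist = twist), class = "HelicalSymmetry")
}

#' @export
print.HelicalSymmetry <- function(x, ...) {
  cat(sprintf("<HelicalSymmetry> rise %.4f A, twist %.4f deg\n",
              x$rise, x$twist))
  invisible(x)
}

#' Build a helical filament from a monomer
#'
#' Subunit k (k = 0 .. n_subunits-1) is the monomer rotated by k*twist about
#' the axis and translated by k*rise along it. Chains are relabeled A, B, C,
#' ... in subunit order.
#'
#' @param monomer a single-chain [atomic_model()].
#' @param sym a [helical_symmetry()].
#' @param n_subunits number of subunits (>= 2).
#' @param axis rotation/translation axis (default z).
#' @return an [atomic_model()] of the filament.
#' @export
build_filament <- function(monomer, sym, n_subunits, axis = c(0, 0, 1)) {
  if (n_subunits < 2) hf_error("n_subunits must be >= 2")
  if (length(unique(monomer$chain)) != 1)
    hf_error("monomer must have a single chain")
  if (n_subunits > 26) hf_error("more than 26 subunits exceed chain labels A-Z")
  u <- unitv(axis)
  subunits <- vector("list", n_subunits)
  for (k in seq_len(n_subunits) - 1L) {
    R <- rotation_about_axis(u, k * sym$twist)
    sub <- transform_model(monomer, R, k * sym$rise * u)
    sub$chain <- LETTERS[k + 1L]
    subunits[[k + 1L]] <- sub
  }
  out <- do.call(rbind, lapply(subunits, as.data.frame))
  as_atomic_model(out)
}

# Decompose a rigid transform (R, t) into screw parameters. The axis sign is
# chosen so that the rise (translation along the axis) is positive; the twist
# is then the signed right-handed rotation angle about that axis. Exactly-180
# rotations have an undefined twist sign and raise an error (per the module's
# tie-break rule); near-zero rotations have an undefined axis and also error.
screw_decompose <- function(R, t) {
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  s <- vnorm(w)
  if (s < 1e-9) {
    if (ct > 0) hf_error("rotation angle near 0: screw axis undefined")
    # exactly-180 rotation: the sign is immaterial, report +180 by convention
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    u <- Re(ev$vectors[, k]); u <- u / vnorm(u)
    rise <- sum(t * u)
    if (rise < 0) { u <- -u; rise <- -rise }
    M <- diag(3) - R + outer(u, u)
    p <- drop(solve(M, t - rise * u))
    return(list(rise = rise, twist = 180, axis = u, axis_point = p))
  }
  u <- w / s
  rise <- sum(t * u)
  if (rise < 0) { u <- -u; rise <- -rise }
  twist <- rad2deg(atan2(sum(w * u), ct))
  # fixed point of the screw in the plane perpendicular to the axis:
  # (I - R + u u^T) p = t - rise*u has a unique solution with p . u = 0
  M <- diag(3) - R + outer(u, u)
  p <- drop(solve(M, t - rise * u))
  list(rise = rise, twist = twist, axis = u, axis_point = p)
}

#' Estimate helical symmetry from a filament model
#'
#' For each consecutive pair of chains, superposes the shared C-alpha set of
#' one subunit onto the next (least squares) and decomposes the optimal rigid
#' transform into screw parameters: signed twist about the screw axis and rise
#' along it. The mean symmetry is the arithmetic mean of the per-interface
#' values.
#'
#' @param filament an [atomic_model()] with >= 2 chains.
#' @param chain_order chain ids in subunit order (default: order of
#'   appearance).
#' @return an object of class `SymmetryEstimate`: fields `mean_symmetry`
#'   ([helical_symmetry()]), `per_interface` (data.frame of rise/twist per
#'   consecutive pair), `axis` (unit vector), `axis_point` (Angstrom).
#' @export
estimate_symmetry <- function(filament, chain_order = NULL) {
  if (is.null(chain_order)) chain_order <- unique(filament$chain)
  if (length(chain_order) < 2) hf_error("need at least 2 chains")
  cas <- lapply(chain_order, function(ch) {
    m <- model_subset(filament, filament$chain == ch & filament$atom == "CA")
    if (nrow(m) < 3) hf_error(sprintf("chain %s has < 3 CA atoms", ch))
    m
  })
  per <- vector("list", length(cas) - 1)
  axes <- matrix(0, length(per), 3)
  pts <- matrix(0, length(per), 3)
  for (i in seq_along(per)) {
    a <- cas[[i]]; b <- cas[[i + 1]]
    shared <- intersect(a$resno, b$resno)
    if (length(shared) < 3)
      hf_error(sprintf("chains %s/%s share < 3 CA residues",
                       chain_order[i], chain_order[i + 1]))
    P <- model_coords(model_subset(a, match(shared, a$resno)))
    Q <- model_coords(model_subset(b, match(shared, b$resno)))
    fit <- kabsch(P, Q)
    sc <- screw_decompose(fit$R, fit$t)
    per[[i]] <- data.frame(interface = i, rise = sc$rise, twist = sc$twist)
    axes[i, ] <- sc$axis
    pts[i, ] <- sc$axis_point
  }
  per <- do.call(rbind, per)
  mean_axis <- unitv(colMeans(axes))
  structure(list(
    mean_symmetry = helical_symmetry(mean(per$rise), mean(per$twist)),
    per_interface = per,
    axis = mean_axis,
    axis_point = pts[1, ]), class = "SymmetryEstimate")
}

#' @export
print.SymmetryEstimate <- function(x, ...) {
  cat(sprintf(
    "<SymmetryEstimate> %d interfaces; mean rise %.4f A, mean twist %.4f deg\n",
    nrow(x$per_interface), x$mean_symmetry$rise, x$mean_symmetry$twist))
  invisible(x)
}

#' Cross-over distance of a two-start helix
#'
#' The axial length over which the two long-pitch strands of an actin-like
#' filament cross: `rise * 180 / (180 - |twist|)`.
#'
#' @param sym a [helical_symmetry()] (|twist| must differ from 180).
#' @return cross-over distance in Angstrom.
#' @examples
#' crossover_distance(helical_symmetry(27.5, -167.2))  # 386.72 A
#' @export
crossover_distance <- function(sym) {
  if (abs(abs(sym$twist) - 180) < 1e-12)
    hf_error("|twist| = 180 degrees: cross-over distance undefined")
  sym$rise * 180 / (180 - abs(sym$twist))
}

#' Compare twist distributions of two symmetry estimates
#'
#' Welch (unequal-variance) two-sample t-test on the per-interface twist
#' values; the sign of the mean difference is `a - b`.
#'
#' @param a,b `SymmetryEstimate` objects with >= 2 interfaces each.
#' @return list with `mean_difference` (degrees, a - b) and `p_value`
#'   (two-sided).
#' @export
compare_twist <- function(a, b) {
  ta <- a$per_interface$twist; tb <- b$per_interface$twist
  if (length(ta) < 2 || length(tb) < 2)
    hf_error("need >= 2 per-interface samples on each side")
  diff <- mean(ta) - mean(tb)
  if (sd(ta) < 1e-12 && sd(tb) < 1e-12) {
    p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    p <- stats::t.test(ta, tb, var.equal = FALSE)$p.value
  }
  list(mean_difference = diff, p_value = p)
}
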