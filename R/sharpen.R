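#' 3x3x3 boxcar low-pass filter
#'
#' Replaces each voxel by the mean of its 3x3x3 neighborhood. Edges are
#' handled by nearest-edge replication (clamped indices), which avoids the rim
#' artifacts zero padding would create.
#'
#' @param map a [density_map()] with all dimensions >= 3.
#' @return the filtered [density_map()].
#' @export
boxcar_lowpass <- function(map) {
  d <- dim(map$grid)
  if (any(d < 3)) hf_error("grid too small for a 3x3x3 kernel")
  g <- map$grid
  clamp <- function(n, s) pmin(pmax(seq_len(n) + s, 1L), n)
  out <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    out <- out + g[clamp(d[1], dx), clamp(d[2], dy), clamp(d[3], dz)]
  }
  density_map(out / 27, map$voxel_size, map$origin)
}

#' Real-space high-boost sharpening
#'
#' Subtracts a weighted 3x3x3 boxcar low-pass copy from the original map:
#' `out = map - factor * lowpass(map)`. This is a 3D high-boost filter: high
#' spatial frequencies are enhanced without eliminating low-frequency
#' information (and it is not equivalent to B-factor sharpening). Factor 0 is
#' the identity.
#'
#' @param map a [density_map()].
#' @param factor sharpening weight (>= 0).
#' @return the sharpened [density_map()] (same grid/voxel/origin).
#' @export
high_boost <- function(map, factor) {
  if (!is.finite(factor) || factor < 0)
    hf_error("sharpening factor must be >= 0")
  lp <- boxcar_lowpass(map)
  density_map(map$grid - factor * lp$grid, map$voxel_size, map$origin)
}

# Residues with a chi1 angle and a gamma heavy atom.
chi1_eligible <- function(resname) {
  !(resname %in% c("GLY", "ALA", "PRO"))
}

#' Side-chain chi1 map-model score
#'
#' An EMRinger-style map-model validation statistic. For every residue with a
#' gamma position (all standard residues except Gly, Ala, Pro) the idealized
#' C-beta/gamma bond is swept about the chi1 axis (defined by N, CA, CB) in
#' `360/n_angles`-degree steps; the map is interpolated at each candidate
#' gamma position and the peak angle recorded. A peak is rotameric when it
#' falls within 30 degrees (inclusive) of 60, 180 or 300. At each threshold t
#' of an even grid from 0 to the map maximum, residues with peak value >= t
#' are included and the rotamer enrichment is summarized as
#' `z(t) = (n_rot - n p0) / sqrt(n p0 (1 - p0))` with p0 the rotameric
#' fraction of the angle grid (39/72 at 5-degree sampling). The score is the
#' maximum z over thresholds retaining at least `n_min` residues.
#'
#' The score is invariant under uniform positive scaling of the map values:
#' peak angles depend only on ranks along the chi1 ring and the threshold grid
#' rescales with the map maximum.
#'
#' @param map a [density_map()] covering the model.
#' @param model an [atomic_model()].
#' @param n_angles chi1 sampling count (default 72, i.e. 5-degree steps).
#' @param n_thresholds number of thresholds in the grid (default 20).
#' @param n_min minimum residues retained at a scoring threshold (default 10).
#' @return an object of class `Chi1ScoreReport`: `per_residue` data.frame
#'   (chain, resno, resname, peak_angle, peak_value, rotameric),
#'   `threshold_trace` data.frame (threshold, n_included, n_rotameric, z),
#'   `score`, and `p0`.
#' @export
chi1_map_score <- function(map, model, n_angles = 72, n_thresholds = 20,
                           n_min = 10) {
  validate_atomic_model(model)
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  rot_grid <- rotameric_angle(angles)
  p0 <- mean(rot_grid)
  key <- paste(model$chain, model$resno)
  res <- list()
  for (grp in split(seq_len(nrow(model)), factor(key, unique(key)))) {
    sub <- model[grp, ]
    if (!chi1_eligible(sub$resname[1])) next
    iN <- match("N", sub$atom); iCA <- match("CA", sub$atom)
    iCB <- match("CB", sub$atom)
    if (any(is.na(c(iN, iCA, iCB)))) next
    pos <- place_atoms(c(sub$x[iN], sub$y[iN], sub$z[iN]),
                       c(sub$x[iCA], sub$y[iCA], sub$z[iCA]),
                       c(sub$x[iCB], sub$y[iCB], sub$z[iCB]),
                       1.52, 113.8, angles)
    vals <- interpolate_map(map, pos)
    if (all(is.na(vals))) next  # residue entirely outside the map
    vals[is.na(vals)] <- -Inf
    k <- which.max(vals)
    res[[length(res) + 1]] <- data.frame(
      chain = sub$chain[1], resno = sub$resno[1], resname = sub$resname[1],
      peak_angle = angles[k], peak_value = vals[k],
      rotameric = rot_grid[k], stringsAsFactors = FALSE)
  }
  if (!length(res)) hf_error("no chi1-eligible residues covered by the map")
  per <- do.call(rbind, res)
  thresholds <- seq(0, max(map$grid), length.out = n_thresholds)
  trace <- data.frame(threshold = thresholds, n_included = NA_integer_,
                      n_rotameric = NA_integer_, z = NA_real_)
  for (i in seq_len(n_thresholds)) {
    inc <- per$peak_value >= thresholds[i]
    n <- sum(inc)
    trace$n_included[i] <- n
    trace$n_rotameric[i] <- sum(per$rotameric[inc])
    if (n >= n_min)
      trace$z[i] <- (trace$n_rotameric[i] - n * p0) / sqrt(n * p0 * (1 - p0))
  }
  score <- if (all(is.na(trace$z))) NA_real_ else max(trace$z, na.rm = TRUE)
  structure(list(per_residue = per, threshold_trace = trace, score = score,
                 p0 = p0), class = "Chi1ScoreReport")
}

rotameric_angle <- function(angle) {
  a <- angle %% 360
  (abs(((a - 60 + 180) %% 360) - 180) <= 30) |
    (abs(((a - 180 + 180) %% 360) - 180) <= 30) |
    (abs(((a - 300 + 180) %% 360) - 180) <= 30)
}

#' Masked map-model correlation
#'
#' Pearson correlation between the map and a model-derived Gaussian-atom map,
#' restricted to voxels within `mask_radius` of any model atom.
#'
#' @param map a [density_map()] covering the model.
#' @param model an [atomic_model()].
#' @param mask_radius mask radius around atoms, Angstrom.
#' @param b_offset blur used for the model map, Angstrom^2.
#' @return the correlation (scalar in [-1, 1]).
#' @export
masked_correlation <- function(map, model, mask_radius = 3, b_offset = 20) {
  d <- dim(map$grid)
  ax <- lapply(1:3, function(k) map_axis(map, k))
  mask <- model_voxel_mask(map, model, mask_radius)
  if (!any(mask)) hf_error("empty mask: no voxels near the model")
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  mv <- model_density_at(model, pts, b_offset)
  stats::cor(map$grid[mask], mv)
}

# Gaussian-atom density evaluated analytically at arbitrary points; matches
# the model_to_map kernel (same variance, amplitude and 4.5-sigma cutoff).
model_density_at <- function(model, pts, b_offset = 20) {
  zed <- element_z(model$element)
  sig2 <- pmax(model$b + b_offset, 1e-2) / (8 * pi^2)
  xyz <- model_coords(model)
  out <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    d2 <- (pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
      (pts[, 3] - xyz[a, 3])^2
    sel <- d2 <= 20.25 * sig2[a]  # 4.5-sigma radius, as in model_to_map
    amp <- zed[a] * model$occ[a] / (2 * pi * sig2[a])^1.5
    out[sel] <- out[sel] + amp * exp(-d2[sel] / (2 * sig2[a]))
  }
  out
}

#' Score-driven sharpening factor optimization
#'
#' Evaluates a map-model scorer on `high_boost(map, f)` for every factor in an
#' ascending grid and returns the trace and the best factor (ties broken
#' toward the smaller factor). This mirrors score-maximizing sharpening
#' optimization; note the model is rescored as-is at every factor (no
#' per-factor model re-refinement is attempted).
#'
#' @param map a [density_map()].
#' @param model an [atomic_model()].
#' @param scorer "chi1" or "masked_corr".
#' @param factor_grid ascending non-empty numeric vector of factors (>= 0).
#' @param ... passed on to the scorer.
#' @return an object of class `SharpeningResult`: `best_factor`, `trace`
#'   (data.frame factor/score), `sharpened_map` (map at the best factor).
#' @export
optimize_sharpening <- function(map, model, scorer = c("chi1", "masked_corr"),
                                factor_grid = seq(0, 1.5, by = 0.25), ...) {
  scorer <- match.arg(scorer)
  if (!length(factor_grid) || is.unsorted(factor_grid, strictly = TRUE))
    hf_error("factor_grid must be non-empty and strictly ascending")
  score_fun <- switch(scorer,
    chi1 = function(m) chi1_map_score(m, model, ...)$score,
    masked_corr = function(m) masked_correlation(m, model, ...))
  scores <- numeric(length(factor_grid))
  best_map <- NULL
  for (i in seq_along(factor_grid)) {
    sm <- high_boost(map, factor_grid[i])
    scores[i] <- tryCatch(score_fun(sm), error = function(e)
      hf_error(sprintf("scorer failed at factor %g: %s",
                       factor_grid[i], conditionMessage(e))))
    if (i == which.max(scores[seq_len(i)])) best_map <- sm
  }
  best <- which.max(scores)  # first maximum: ties go to the smaller factor
  structure(list(best_factor = factor_grid[best],
                 trace = data.frame(factor = factor_grid, score = scores),
                 sharpened_map = high_boost(map, factor_grid[best])),
            class = "SharpeningResult")
}

#' Fourier B-factor sharpening
#'
#' Scales Fourier amplitudes by `exp(-b s^2 / 4)` (s = spatial frequency,
#' 1/Angstrom) up to the resolution limit and low-passes beyond it. Negative b
#' sharpens; this is the classic global B-factor baseline against which
#' high-boost sharpening is compared.
#'
#' @param map a [density_map()].
#' @param b B-factor in Angstrom^2 (<= 0 for sharpening).
#' @param resolution_limit resolution cutoff in Angstrom (> 0); frequencies
#'   beyond 1/resolution_limit are zeroed.
#' @return the filtered [density_map()].
#' @export
bfactor_sharpen <- function(map, b, resolution_limit) {
  if (!is.finite(resolution_limit) || resolution_limit <= 0)
    hf_error("resolution_limit must be positive")
  d <- dim(map$grid)
  fr <- function(n, step) {
    f <- 0:(n - 1)
    f[f > n / 2] <- f[f > n / 2] - n
    f / (n * step)
  }
  fx <- fr(d[1], map$voxel_size[1])
  fy <- fr(d[2], map$voxel_size[2])
  fz <- fr(d[3], map$voxel_size[3])
  s2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  scale <- exp(-b * s2 / 4)
  scale[s2 > 1 / resolution_limit^2] <- 0
  ft <- stats::fft(map$grid) * scale
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  density_map(out, map$voxel_size, map$origin)
}
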