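#' Density map container
#'
#' A `DensityMap` holds a 3D scalar grid together with the voxel size (Angstrom
#' per voxel along x, y, z) and the world-space origin, i.e. the position of
#' grid index (1,1,1). The world coordinate of 1-based index (i,j,k) is
#' `origin + (i-1, j-1, k-1) * voxel_size`, exactly. Grids are stored in
#' canonical x-fastest order.
#'
#' @param grid 3D numeric array (each dimension >= 3).
#' @param voxel_size length-3 (or scalar) positive voxel size in Angstrom.
#' @param origin length-3 origin in Angstrom.
#' @return an object of class `DensityMap`.
#' @export
density_map <- function(grid, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3)
    hf_error("grid must be a 3D array")
  if (any(dim(grid) < 3)) hf_error("grid dimensions must all be >= 3")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) hf_error("voxel sizes must be positive")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<DensityMap> %dx%dx%d voxels @ (%.3f, %.3f, %.3f) A, origin (%.2f, %.2f, %.2f)\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# Voxel-center axis coordinates of a map along dimension k.
map_axis <- function(map, k) {
  map$origin[k] + (seq_len(dim(map$grid)[k]) - 1) * map$voxel_size[k]
}

#' Trilinear map interpolation
#'
#' Interpolates map values at arbitrary points from the 8 surrounding voxel
#' centers. Points outside the grid bounding box give `NA` (the caller decides
#' how to treat the out-of-bounds signal).
#'
#' @param map a [density_map()].
#' @param points length-3 vector or n x 3 matrix of points (Angstrom).
#' @return numeric vector of interpolated values (NA outside the box).
#' @export
interpolate_map <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  d <- dim(map$grid)
  f <- sweep(sweep(points, 2, map$origin), 2, map$voxel_size, "/")
  i0 <- floor(f)
  w <- f - i0
  ok <- f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0 &
    f[, 1] <= d[1] - 1 & f[, 2] <= d[2] - 1 & f[, 3] <= d[3] - 1
  # clamp the base cell so points exactly on the upper face interpolate cleanly
  i0 <- pmin(pmax(i0, 0), matrix(rep(d - 2, each = nrow(f)), ncol = 3))
  w <- f - i0
  out <- rep(NA_real_, nrow(f))
  if (any(ok)) {
    g <- map$grid
    ii <- i0[ok, 1, drop = TRUE] + 1L; jj <- i0[ok, 2, drop = TRUE] + 1L
    kk <- i0[ok, 3, drop = TRUE] + 1L
    wx <- w[ok, 1, drop = TRUE]; wy <- w[ok, 2, drop = TRUE]
    wz <- w[ok, 3, drop = TRUE]
    v <- (1 - wx) * (1 - wy) * (1 - wz) * g[cbind(ii, jj, kk)] +
      wx * (1 - wy) * (1 - wz) * g[cbind(ii + 1L, jj, kk)] +
      (1 - wx) * wy * (1 - wz) * g[cbind(ii, jj + 1L, kk)] +
      (1 - wx) * (1 - wy) * wz * g[cbind(ii, jj, kk + 1L)] +
      wx * wy * (1 - wz) * g[cbind(ii + 1L, jj + 1L, kk)] +
      wx * (1 - wy) * wz * g[cbind(ii + 1L, jj, kk + 1L)] +
      (1 - wx) * wy * wz * g[cbind(ii, jj + 1L, kk + 1L)] +
      wx * wy * wz * g[cbind(ii + 1L, jj + 1L, kk + 1L)]
    out[ok] <- v
  }
  out
}

#' Synthesize a model-derived density map
#'
#' Each atom contributes an isotropic 3D Gaussian whose variance is
#' `(b + b_offset) / (8 pi^2)` (the standard B-factor/displacement relation)
#' and whose integral equals atomic number times occupancy. This is the simple
#' Gaussian-atom model (amplitude proportional to Z, not full scattering
#' factors): adequate for difference-peak detection and map-model scoring.
#'
#' @param model an [atomic_model()].
#' @param voxel_size voxel size in Angstrom (> 0).
#' @param padding box padding around the model extent, Angstrom.
#' @param b_offset additional blur added to every atomic B-factor, Angstrom^2.
#' @return a [density_map()] whose origin is the padded lower box corner.
#' @export
model_to_map <- function(model, voxel_size = 1, padding = 5, b_offset = 20) {
  if (voxel_size <= 0) hf_error("voxel_size must be > 0")
  validate_atomic_model(model)
  xyz <- model_coords(model)
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(ceiling((hi - lo) / voxel_size) + 1L, 3L)
  grid <- array(0, dims)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * voxel_size)
  zed <- element_z(model$element)
  sig2 <- pmax(model$b + b_offset, 1e-2) / (8 * pi^2)
  for (a in seq_len(nrow(xyz))) {
    cut <- 4.5 * sqrt(sig2[a])
    ir <- lapply(1:3, function(k) which(abs(ax[[k]] - xyz[a, k]) <= cut))
    if (any(lengths(ir) == 0)) next
    dx2 <- (ax[[1]][ir[[1]]] - xyz[a, 1])^2
    dy2 <- (ax[[2]][ir[[2]]] - xyz[a, 2])^2
    dz2 <- (ax[[3]][ir[[3]]] - xyz[a, 3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    amp <- zed[a] * model$occ[a] / (2 * pi * sig2[a])^1.5
    blob <- amp * exp(-r2 / (2 * sig2[a]))
    blob[r2 > cut^2] <- 0  # spherical cutoff, same as model_density_at
    grid[ir[[1]], ir[[2]], ir[[3]]] <- grid[ir[[1]], ir[[2]], ir[[3]]] + blob
  }
  density_map(grid, voxel_size, lo)
}

# Logical mask of voxels within `radius` of any model atom.
model_voxel_mask <- function(map, model, radius) {
  d <- dim(map$grid)
  mask <- array(FALSE, d)
  ax <- lapply(1:3, function(k) map_axis(map, k))
  xyz <- model_coords(model)
  r2 <- radius^2
  for (a in seq_len(nrow(xyz))) {
    ir <- lapply(1:3, function(k)
      which(abs(ax[[k]] - xyz[a, k]) <= radius))
    if (any(lengths(ir) == 0)) next
    dx2 <- (ax[[1]][ir[[1]]] - xyz[a, 1])^2
    dy2 <- (ax[[2]][ir[[2]]] - xyz[a, 2])^2
    dz2 <- (ax[[3]][ir[[3]]] - xyz[a, 3])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    mask[ir[[1]], ir[[2]], ir[[3]]] <- mask[ir[[1]], ir[[2]], ir[[3]]] | within
  }
  mask
}
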