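#' Read an MRC2014 density map
#'
#' Reads little-endian MRC/CCP4 maps (modes 0, 1, 2). Axis-permuted maps
#' (mapc/mapr/maps other than 1,2,3) are returned with the grid reordered to
#' canonical x-fastest order. The voxel size comes from `cella / (mx,my,mz)`.
#'
#' Two origin dialects occur in EMDB depositions: the `origin` float record and
#' the `nstart` integer offsets. With `origin_mode = "auto"` (default) the
#' origin record is used when any component is nonzero, otherwise
#' `nstart * voxel_size`.
#'
#' @param path file path.
#' @param origin_mode one of "auto", "origin", "nstart".
#' @return a [density_map()].
#' @export
read_map <- function(path, origin_mode = c("auto", "origin", "nstart")) {
  origin_mode <- match.arg(origin_mode)
  if (!file.exists(path)) hf_error(sprintf("cannot read map file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) hf_error("truncated MRC header")
  magic <- rawToChar(hdr_raw[209:212])
  if (!startsWith(magic, "MAP")) hf_error("not an MRC2014 file (missing MAP magic)")
  int_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)],
                                "integer", size = 4, endian = "little")
  flt_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)],
                                "numeric", size = 4, endian = "little")
  nxyz <- sapply(1:3, int_at)
  mode <- int_at(4)
  nstart <- sapply(5:7, int_at)
  mxyz <- sapply(8:10, int_at)
  cella <- sapply(11:13, flt_at)
  mapcrs <- sapply(17:19, int_at)
  nsymbt <- int_at(24)
  origin_rec <- sapply(50:52, flt_at)
  if (!all(sort(mapcrs) == 1:3)) hf_error("inconsistent MRC axis order header")
  if (any(nxyz < 1) || any(mxyz < 1)) hf_error("inconsistent MRC dimensions")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  nvox <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    hf_error(sprintf("unsupported MRC mode %d", mode)))
  if (length(vals) < nvox) hf_error("truncated MRC data block")
  arr <- array(vals, nxyz)  # dims in file order: fastest, medium, slow
  # crystal-axis voxel size; columns/rows/sections map to axes mapcrs
  voxel_xyz <- cella / mxyz
  perm <- match(1:3, mapcrs)          # new dim k comes from file dim perm[k]
  arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]
  origin <- switch(origin_mode,
    origin = origin_rec,
    nstart = nstart_xyz * voxel_xyz,
    auto = if (any(origin_rec != 0)) origin_rec else nstart_xyz * voxel_xyz)
  density_map(arr, voxel_xyz, origin)
}

#' Write an MRC2014 density map
#'
#' Writes mode-2 (float32) little-endian MRC with canonical axis order. By
#' default the origin is stored in the `origin` float record; with
#' `use_nstart = TRUE` it is stored as integer `nstart` offsets instead (the
#' origin must then be an integer multiple of the voxel size).
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @param use_nstart store origin via nstart offsets instead of the origin
#'   record.
#' @return invisibly, the path written.
#' @export
write_map <- function(map, path, use_nstart = FALSE) {
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  g <- map$grid
  nstart <- c(0L, 0L, 0L)
  origin_rec <- map$origin
  if (use_nstart) {
    ns <- map$origin / map$voxel_size
    if (any(abs(ns - round(ns)) > 1e-6))
      hf_error("origin is not a voxel multiple; cannot encode as nstart")
    nstart <- as.integer(round(ns))
    origin_rec <- c(0, 0, 0)
  }
  wi(d)                                   # nx ny nz
  wi(2L)                                  # mode 2: float32
  wi(nstart)                              # nstart
  wi(d)                                   # mx my mz
  wf(d * map$voxel_size)                  # cella
  wf(c(90, 90, 90))                       # cellb
  wi(1:3)                                 # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))          # dmin dmax dmean
  wi(c(1L, 0L))                           # ispg, nsymbt
  wi(rep(0L, 25))                         # extra
  wf(origin_rec)                          # origin x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machst
  wf(sd(as.numeric(g)))                   # rms
  wi(0L)                                  # nlabl
  writeBin(raw(800), con)                 # labels
  wf(as.numeric(g))
  invisible(path)
}
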