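# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; no binary fixtures ship with the package.

# A tiny rigid transform used in invariance tests.
rigid37 <- function() {
  list(R = helixforge:::rotation_about_axis(c(1, 2, 3), 37),
       t = c(3.1, -2.4, 7.9))
}

# Independent brute-force gRMSD oracle: recursive permutation enumeration and
# direct angle arithmetic, sharing no code with geometry_grmsd().
oracle_grmsd <- function(metal, ligands, geometry) {
  ideal <- helixforge:::ideal_geometry_vertices(geometry)
  n <- nrow(ideal)
  ang <- function(u, v) {
    ct <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
    acos(max(-1, min(1, ct))) * 180 / pi
  }
  obs <- lapply(seq_len(n), function(i) ligands[i, ] - metal)
  best <- Inf
  rec <- function(assign, used) {
    if (length(assign) == n) {
      ss <- 0; cnt <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        d <- ang(obs[[i]], obs[[j]]) - ang(ideal[assign[i], ], ideal[assign[j], ])
        ss <- ss + d^2; cnt <- cnt + 1
      }
      best <<- min(best, sqrt(ss / cnt))
      return()
    }
    for (v in seq_len(n)[!used]) {
      used[v] <- TRUE
      rec(c(assign, v), used)
      used[v] <- FALSE
    }
  }
  rec(integer(0), rep(FALSE, n))
  best
}

# Low-level MRC writer used only to craft axis-permuted / nstart fixtures
# independently of write_map(). `mapcrs` gives (mapc, mapr, maps); the grid is
# supplied in canonical x,y,z order and permuted into file order here.
write_mrc_raw <- function(path, grid, voxel, mapcrs = c(1L, 2L, 3L),
                          nstart = c(0L, 0L, 0L), origin = c(0, 0, 0)) {
  arr <- aperm(grid, mapcrs)              # file dim f = canonical dim mapcrs[f]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dim(arr)); wi(2L)
  wi(nstart[mapcrs])                      # nstart per file axis
  wi(dim(grid))                           # mx,my,mz are per crystal axis
  wf(dim(grid) * voxel)                   # cella per crystal axis
  wf(c(90, 90, 90))
  wi(mapcrs)
  wf(c(min(arr), max(arr), mean(arr)))
  wi(c(1L, 0L)); wi(rep(0L, 25))
  wf(origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(stats::sd(as.numeric(arr))); wi(0L)
  writeBin(raw(800), con)
  wf(as.numeric(arr))
  invisible(path)
}

# float32-exact random grid values (dyadic rationals), for lossless
# round-trips through mode-2 MRC.
f32_grid <- function(dims, seed = 1) {
  set.seed(seed)
  array(round(runif(prod(dims)) * 1000) / 1024, dims)
}
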