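# Candidate cation-site evaluation: coordinating-atom search, ideal-geometry
# angle RMSD (gRMSD), bond-valence vector sums, difference-density peak
# picking and a rule-based Mg2+/K+/water plausibility ranking.

# Ideal coordination geometries as unit vertex vectors.
ideal_geometry_vertices <- function(geometry) {
  switch(geometry,
    octahedral = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1)),
    trigonal_bipyramidal = rbind(
      c(0, 0, 1), c(0, 0, -1),
      c(1, 0, 0), c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
      c(cos(4 * pi / 3), sin(4 * pi / 3), 0)),
    square_pyramidal = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                             c(-1, 0, 0), c(0, -1, 0)),
    tetrahedral = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      v / sqrt(3)
    },
    hf_error(sprintf("unsupported coordination geometry: %s", geometry)))
}

# Published bond-valence parameters (b = 0.37 A universally); shipped as an
# editable table because the source analyses delegate these constants to an
# external server without printing them.
bond_valence_r0 <- function() {
  data.frame(
    metal = c("MG", "MG", "K", "K", "NA", "CA", "ZN", "MN"),
    ligand = c("O", "N", "O", "N", "O", "O", "O", "O"),
    r0 = c(1.693, 1.85, 2.132, 2.26, 1.803, 1.967, 1.704, 1.79),
    stringsAsFactors = FALSE)
}

#' Find metal-coordinating atoms
#'
#' Returns all O/N donor atoms (including waters) strictly within `cutoff` of
#' a candidate site, sorted by distance. Hydrogens and any atom exactly at the
#' center (the metal itself) are excluded. The default cutoff 2.6 Angstrom is
#' the Mg2+ coordination distance.
#'
#' @param model an [atomic_model()].
#' @param center length-3 site position, Angstrom.
#' @param cutoff donor search radius, Angstrom (> 0; strict inequality).
#' @param donor_elements element symbols accepted as donors.
#' @return a data.frame of ligand atoms with a `distance` column (possibly
#'   empty).
#' @export
find_coordinating_atoms <- function(model, center, cutoff = 2.6,
                                    donor_elements = c("O", "N")) {
  if (cutoff <= 0) hf_error("cutoff must be positive")
  xyz <- model_coords(model)
  dist <- sqrt(colSums((t(xyz) - center)^2))
  keep <- model$element %in% toupper(donor_elements) &
    dist < cutoff & dist > 1e-6
  out <- as.data.frame(model[keep, , drop = FALSE])
  out$distance <- dist[keep]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Angle RMSD against an ideal coordination geometry (gRMSD)
#'
#' For every assignment of the observed ligands to the vertices of the ideal
#' polyhedron (exhaustive; vertex counts here are <= 6), computes the RMSD
#' between observed ligand-metal-ligand angles and the corresponding ideal
#' vertex-vertex angles, and returns the minimum over assignments. Smaller is
#' better; a perfect polyhedron scores 0. The measure is invariant under rigid
#' motion, uniform scaling and ligand relabeling.
#'
#' @param metal_position length-3 metal position, Angstrom.
#' @param ligand_positions n x 3 matrix of ligand positions.
#' @param geometry one of "octahedral", "trigonal_bipyramidal",
#'   "square_pyramidal", "tetrahedral".
#' @return the minimal angle RMSD in degrees.
#' @export
geometry_grmsd <- function(metal_position, ligand_positions, geometry) {
  ideal <- ideal_geometry_vertices(geometry)
  n <- nrow(ideal)
  if (is.null(dim(ligand_positions)))
    ligand_positions <- matrix(ligand_positions, ncol = 3)
  if (nrow(ligand_positions) != n)
    hf_error(sprintf("%s geometry needs %d ligands, got %d",
                     geometry, n, nrow(ligand_positions)))
  u <- t(apply(ligand_positions, 1, function(p) unitv(p - metal_position)))
  obs_ang <- pair_angles(u)
  ideal_ang <- pair_angles(ideal)
  perms <- all_permutations(n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    # ligand i sits on vertex p[i]; compare angle(i,j) to ideal angle(p_i,p_j)
    diffs <- obs_ang[pairs] - ideal_ang[cbind(p[pairs[, 1]], p[pairs[, 2]])]
    v <- sqrt(mean(diffs^2))
    if (v < best) best <- v
  }
  best
}

# Symmetric matrix of pairwise angles (degrees) between unit vectors.
pair_angles <- function(u) {
  ct <- u %*% t(u)
  ct[ct > 1] <- 1; ct[ct < -1] <- -1
  rad2deg(acos(ct))
}

#' Bond-valence vector sum (vecsum)
#'
#' Each metal-ligand bond gets a valence `s_i = exp((r0 - r_i)/0.37)`; the
#' vecsum is `|sum s_i u_i| / sum s_i` with `u_i` the metal-to-ligand unit
#' vectors. It lies in [0, 1]: 0 for a centrosymmetric equal-distance shell,
#' 1 for a single ligand. By the bond-valence vector-sum convention smaller
#' means a more symmetric, more plausible coordination; note some authors
#' gloss the normalized variant in the opposite sense.
#'
#' @param metal_element metal element symbol (e.g. "MG", "K").
#' @param metal_position length-3 metal position, Angstrom.
#' @param ligands data.frame with `x`, `y`, `z` and `element` columns (as
#'   returned by [find_coordinating_atoms()]).
#' @return the vecsum (dimensionless, in [0, 1]).
#' @export
bond_valence_vecsum <- function(metal_element, metal_position, ligands) {
  if (nrow(ligands) < 1) hf_error("need at least one ligand")
  tab <- bond_valence_r0()
  r0 <- tab$r0[match(paste(toupper(metal_element), ligands$element),
                     paste(tab$metal, tab$ligand))]
  if (any(is.na(r0)))
    hf_error(sprintf("no bond-valence r0 for %s-%s", toupper(metal_element),
                     paste(unique(ligands$element[is.na(r0)]), collapse = ",")))
  vec <- sweep(cbind(ligands$x, ligands$y, ligands$z), 2, metal_position)
  r <- sqrt(rowSums(vec^2))
  s <- exp((r0 - r) / 0.37)
  u <- vec / r
  vnorm(colSums(s * u)) / sum(s)
}

#' Evaluate a candidate metal site
#'
#' Convenience wrapper building a full `MetalSiteReport`: coordinating atoms,
#' per-geometry gRMSD (for geometries whose vertex count matches the observed
#' coordination number) and the bond-valence vecsum.
#'
#' @param model an [atomic_model()].
#' @param metal_element element symbol of the candidate cation.
#' @param metal_position length-3 position, Angstrom.
#' @param cutoff coordination search radius, Angstrom.
#' @return an object of class `MetalSiteReport`.
#' @export
metal_site_report <- function(model, metal_element, metal_position,
                              cutoff = 2.6) {
  lig <- find_coordinating_atoms(model, metal_position, cutoff)
  cn <- nrow(lig)
  geoms <- c(octahedral = 6, trigonal_bipyramidal = 5, square_pyramidal = 5,
             tetrahedral = 4)
  gr <- sapply(names(geoms)[geoms == cn], function(g)
    geometry_grmsd(metal_position, cbind(lig$x, lig$y, lig$z), g))
  vs <- if (cn >= 1)
    bond_valence_vecsum(metal_element, metal_position, lig) else NA_real_
  structure(list(metal_element = toupper(metal_element),
                 metal_position = metal_position,
                 ligands = lig, coordination_number = cn,
                 grmsd_by_geometry = gr,
                 best_geometry = if (length(gr)) names(gr)[which.min(gr)]
                                 else NA_character_,
                 vecsum = vs, cutoff = cutoff),
            class = "MetalSiteReport")
}

#' @export
print.MetalSiteReport <- function(x, ...) {
  cat(sprintf("<MetalSiteReport> %s, CN %d, vecsum %s, best geometry %s\n",
              x$metal_element, x$coordination_number,
              ifelse(is.na(x$vecsum), "NA", sprintf("%.3f", x$vecsum)),
              x$best_geometry))
  invisible(x)
}

#' Find unmodeled difference-density peaks
#'
#' Computes a difference map `map - c * model_map` with `c` the least-squares
#' amplitude scale fitted over the model mask, then returns strict
#' 26-neighborhood local maxima with height at least `sigma_threshold` times
#' the difference-map standard deviation and farther than `exclusion_radius`
#' from any model atom, sorted by height (in sigma units, descending). Such
#' peaks flag density that the protein model alone cannot explain (candidate
#' ions or ordered waters).
#'
#' @param map a [density_map()] covering the model.
#' @param model an [atomic_model()].
#' @param exclusion_radius minimum peak-atom distance, Angstrom.
#' @param sigma_threshold detection threshold in difference-map sigma.
#' @param mask_radius radius defining the model mask for amplitude scaling.
#' @param b_offset blur for the model map, Angstrom^2.
#' @return a data.frame of peaks: `x`, `y`, `z`, `height` (sigma units),
#'   `distance_to_nearest_model_atom`.
#' @export
find_unmodeled_peaks <- function(map, model, exclusion_radius = 1.2,
                                 sigma_threshold = 3.0, mask_radius = 2.5,
                                 b_offset = 20) {
  mask <- model_voxel_mask(map, model, mask_radius)
  if (!any(mask)) hf_error("model mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  ax <- lapply(1:3, function(k) map_axis(map, k))
  pts <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  mv_mask <- model_density_at(model, pts, b_offset)
  denom <- sum(mv_mask^2)
  if (denom < 1e-12) hf_error("degenerate scaling: model density is zero")
  cscale <- sum(map$grid[mask] * mv_mask) / denom
  d <- dim(map$grid)
  allpts <- cbind(rep(ax[[1]], times = d[2] * d[3]),
                  rep(rep(ax[[2]], each = d[1]), times = d[3]),
                  rep(ax[[3]], each = d[1] * d[2]))
  diffg <- map$grid - cscale * array(model_density_at(model, allpts, b_offset), d)
  sdv <- sd(as.numeric(diffg))
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      height = numeric(0),
                      distance_to_nearest_model_atom = numeric(0))
  if (sdv < 1e-12) return(empty)
  thr <- sigma_threshold * sdv
  cand <- which(diffg >= thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  # interior strict local maxima over the 26-neighborhood
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
    if (i == 1 || j == 1 || k == 1 || i == d[1] || j == d[2] || k == d[3])
      next
    nb <- diffg[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    v <- diffg[i, j, k]
    nb[2, 2, 2] <- -Inf
    keep[r] <- v > max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  pos <- cbind(ax[[1]][cand[, 1]], ax[[2]][cand[, 2]], ax[[3]][cand[, 3]])
  xyz <- model_coords(model)
  dmin <- apply(pos, 1, function(p) sqrt(min(colSums((t(xyz) - p)^2))))
  h <- diffg[cand] / sdv
  out <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], height = h,
                    distance_to_nearest_model_atom = dmin)
  out <- out[out$distance_to_nearest_model_atom > exclusion_radius, ,
             drop = FALSE]
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank cation/water plausibility for a metal site
#'
#' Rule-based ranking of Mg2+, K+ and water for a characterized site. Rules:
#' mean ligand distance inside the element window (Mg-O 1.9-2.6 A, K-O
#' 2.6-3.2 A), preferred coordination numbers (Mg: 5-6; K: 6-8), low gRMSD
#' (< 10 degrees supports Mg), and under-coordination (<= 3 ligands) favoring
#' water. The output is an ordered label vector with the triggered rules;
#' never a certainty claim. An empty ligand list returns "indeterminate".
#'
#' @param report a `MetalSiteReport` from [metal_site_report()].
#' @return list with `ranking` (character vector), `scores`, and `reasons`
#'   (character vector of fired rules).
#' @export
classify_cation_candidate <- function(report) {
  if (report$coordination_number == 0)
    return(list(ranking = c("indeterminate"), scores = NULL,
                reasons = "no coordinating atoms within the cutoff"))
  dbar <- mean(report$ligands$distance)
  cn <- report$coordination_number
  grmsd <- if (length(report$grmsd_by_geometry))
    min(report$grmsd_by_geometry) else NA_real_
  scores <- c("Mg2+" = 0, "K+" = 0, water = 0)
  reasons <- character()
  fire <- function(lbl, pts, msg) {
    scores[lbl] <<- scores[lbl] + pts
    reasons <<- c(reasons, msg)
  }
  if (dbar >= 1.9 && dbar <= 2.6)
    fire("Mg2+", 2, sprintf("mean distance %.2f A in Mg-O window 1.9-2.6", dbar))
  if (dbar > 2.6 && dbar <= 3.2)
    fire("K+", 2, sprintf("mean distance %.2f A in K-O window 2.6-3.2", dbar))
  if (cn %in% 5:6)
    fire("Mg2+", 1, sprintf("coordination number %d in Mg-preferred 5-6", cn))
  if (cn %in% 6:8)
    fire("K+", 1, sprintf("coordination number %d in K-preferred 6-8", cn))
  if (!is.na(grmsd) && grmsd < 10)
    fire("Mg2+", 1, sprintf("gRMSD %.1f deg < 10 (regular geometry)", grmsd))
  if (cn <= 3)
    fire("water", 2, sprintf("under-coordinated (%d ligands)", cn))
  if (cn <= 3 && dbar >= 2.5 && dbar <= 3.2)
    fire("water", 1, sprintf("mean distance %.2f A hydrogen-bond-like", dbar))
  ranking <- names(scores)[order(-scores)]  # stable: ties keep Mg > K > water
  list(ranking = ranking, scores = scores, reasons = reasons)
}
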