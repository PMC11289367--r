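# Structure comparison: superposition, per-residue deviation maps,
# peptide-flip detection, salt bridges and inter-subunit distance bookkeeping
# for straight and bent filaments. Residue correspondence defaults to
# identical (chain, residue number).

# Paired CA coordinate sets shared by two models, optionally restricted.
paired_ca <- function(a, b, chains = NULL, resno = NULL) {
  ca_a <- ca_subset(a); ca_b <- ca_subset(b)
  key_a <- paste(ca_a$chain, ca_a$resno)
  key_b <- paste(ca_b$chain, ca_b$resno)
  shared <- intersect(key_a, key_b)
  if (!is.null(chains))
    shared <- shared[ca_a$chain[match(shared, key_a)] %in% chains]
  if (!is.null(resno))
    shared <- shared[ca_a$resno[match(shared, key_a)] %in% resno]
  if (!length(shared)) hf_error("no shared CA residues between the models")
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  list(P = model_coords(ca_a)[ia, , drop = FALSE],
       Q = model_coords(ca_b)[ib, , drop = FALSE],
       chain = ca_a$chain[ia], resno = ca_a$resno[ia])
}

#' Least-squares superposition of two models
#'
#' Optimal proper rotation and translation (Kabsch, no reflection) of the
#' mobile model onto the reference over paired C-alpha atoms.
#'
#' @param mobile,reference `AtomicModel`s sharing (chain, resno) C-alphas.
#' @param chains optional chain restriction.
#' @param resno optional residue-number restriction (e.g. a domain range).
#' @return list with `R`, `t`, `rmsd` (Angstrom) and `n` (pairs used).
#' @export
superpose <- function(mobile, reference, chains = NULL, resno = NULL) {
  pr <- paired_ca(mobile, reference, chains, resno)
  fit <- kabsch(pr$P, pr$Q)
  c(fit, list(n = nrow(pr$P)))
}

#' Per-residue C-alpha deviation map
#'
#' Global mode: one superposition on all shared C-alphas, then per-residue
#' C-alpha distances. Local mode: for each residue the models are superposed
#' on the +/- `window` residue neighborhood (same chain) before measuring that
#' residue's deviation; this separates genuine local rearrangement from
#' domain-scale motion.
#'
#' @param a,b `AtomicModel`s (a is the reference frame of the report).
#' @param alignment "global" or "local".
#' @param window half-width of the local alignment window, residues.
#' @return an object of class `ComparisonReport`: `global_rmsd`,
#'   `per_residue` data.frame (chain, resno, deviation), `alignment`,
#'   `aligned_pairs` (n).
#' @export
per_residue_deviation <- function(a, b, alignment = c("global", "local"),
                                  window = 10) {
  alignment <- match.arg(alignment)
  pr <- paired_ca(b, a)  # mobile = b, reference = a
  fit <- kabsch(pr$P, pr$Q)
  moved <- apply_rigid(pr$P, fit$R, fit$t)
  dev_global <- sqrt(rowSums((moved - pr$Q)^2))
  dev <- dev_global
  if (alignment == "local") {
    for (i in seq_along(dev)) {
      sel <- which(pr$chain == pr$chain[i] &
                     abs(pr$resno - pr$resno[i]) <= window)
      if (length(sel) < 3) { dev[i] <- NA_real_; next }
      lf <- kabsch(pr$P[sel, , drop = FALSE], pr$Q[sel, , drop = FALSE])
      ml <- apply_rigid(pr$P[i, , drop = FALSE], lf$R, lf$t)
      dev[i] <- sqrt(sum((ml - pr$Q[i, , drop = FALSE])^2))
    }
  }
  structure(list(global_rmsd = fit$rmsd,
                 per_residue = data.frame(chain = pr$chain, resno = pr$resno,
                                          deviation = dev),
                 alignment = alignment,
                 aligned_pairs = nrow(pr$P)),
            class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat(sprintf(
    "<ComparisonReport> %s alignment, %d pairs, global RMSD %.3f A, max dev %.3f A\n",
    x$alignment, x$aligned_pairs, x$global_rmsd,
    max(x$per_residue$deviation, na.rm = TRUE)))
  invisible(x)
}

#' Detect peptide flips between two models
#'
#' A residue is flagged as flipped when, after superposing the two models on
#' the surrounding C-alpha window, the angle between its carbonyl C->O vectors
#' exceeds `angle_threshold` while the flanking C-alpha deviations (residues i
#' and i+1) both stay below `ca_gate`: the trace is preserved but the peptide
#' plane has rotated. Residues missing backbone C/O in either model are
#' skipped with a warning.
#'
#' @param a,b `AtomicModel`s.
#' @param angle_threshold carbonyl rotation threshold, degrees.
#' @param ca_gate maximum flanking C-alpha deviation, Angstrom.
#' @param window half-width of the superposition window, residues.
#' @return data.frame of flipped residues: chain, resno, angle (degrees),
#'   ca_dev, ca_dev_next.
#' @export
detect_peptide_flips <- function(a, b, angle_threshold = 90, ca_gate = 3.0,
                                 window = 10) {
  pr <- paired_ca(b, a)
  out <- list()
  skipped <- 0L
  getp <- function(m, ch, rn, at) {
    i <- atom_index(m, ch, rn, at, strict = FALSE)
    if (length(i) != 1) return(NULL)
    c(m$x[i], m$y[i], m$z[i])
  }
  for (i in seq_along(pr$resno)) {
    ch <- pr$chain[i]; rn <- pr$resno[i]
    if (!((rn + 1) %in% pr$resno[pr$chain == ch])) next
    Ca <- getp(a, ch, rn, "C"); Oa <- getp(a, ch, rn, "O")
    Cb <- getp(b, ch, rn, "C"); Ob <- getp(b, ch, rn, "O")
    if (is.null(Ca) || is.null(Oa) || is.null(Cb) || is.null(Ob)) {
      skipped <- skipped + 1L
      next
    }
    sel <- which(pr$chain == ch & abs(pr$resno - rn) <= window)
    if (length(sel) < 3) next
    lf <- kabsch(pr$P[sel, , drop = FALSE], pr$Q[sel, , drop = FALSE])
    vb <- drop(lf$R %*% (Ob - Cb))
    va <- Oa - Ca
    ang <- rad2deg(acos(max(-1, min(1, sum(unitv(va) * unitv(vb))))))
    j <- which(pr$chain == ch & pr$resno == rn + 1)[1]
    dev_i <- sqrt(sum((apply_rigid(pr$P[i, , drop = FALSE], lf$R, lf$t) -
                         pr$Q[i, , drop = FALSE])^2))
    dev_n <- sqrt(sum((apply_rigid(pr$P[j, , drop = FALSE], lf$R, lf$t) -
                         pr$Q[j, , drop = FALSE])^2))
    if (ang > angle_threshold && dev_i < ca_gate && dev_n < ca_gate)
      out[[length(out) + 1]] <- data.frame(chain = ch, resno = rn,
                                           angle = ang, ca_dev = dev_i,
                                           ca_dev_next = dev_n)
  }
  if (skipped > 0)
    warning(sprintf("%d residues skipped (missing backbone C/O)", skipped))
  if (!length(out))
    return(data.frame(chain = character(0), resno = integer(0),
                      angle = numeric(0), ca_dev = numeric(0),
                      ca_dev_next = numeric(0)))
  do.call(rbind, out)
}

salt_bridge_atoms <- function() {
  list(acidic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
       basic = list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                    HIS = c("ND1", "NE2")))
}

#' Detect salt bridges
#'
#' Pairs acidic side-chain oxygens (Asp OD1/OD2, Glu OE1/OE2) with basic
#' side-chain nitrogens (Lys NZ, Arg NH1/NH2/NE, His ND1/NE2) and reports, for
#' every acid/base residue pair whose minimum oxygen-nitrogen distance is
#' strictly below the cutoff, that minimum-distance atom pair. The classic
#' criterion for the inter-subunit actin bridge is a side-chain O within 5
#' Angstrom of the Lys side-chain N.
#'
#' @param model an [atomic_model()].
#' @param cutoff distance cutoff, Angstrom.
#' @param inter_chain_only drop intra-chain pairs.
#' @return data.frame with acidic/basic chain, resno, resname, atom and the
#'   distance, sorted by distance.
#' @export
detect_salt_bridges <- function(model, cutoff = 5.0, inter_chain_only = FALSE) {
  sb <- salt_bridge_atoms()
  pick <- function(defs) {
    keep <- rep(FALSE, nrow(model))
    for (rn in names(defs))
      keep <- keep | (model$resname == rn & model$atom %in% defs[[rn]])
    model_subset(model, keep)
  }
  ac <- pick(sb$acidic); ba <- pick(sb$basic)
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      resname_a = character(0), atom_a = character(0),
                      chain_b = character(0), resno_b = integer(0),
                      resname_b = character(0), atom_b = character(0),
                      distance = numeric(0))
  if (nrow(ac) == 0 || nrow(ba) == 0) return(empty)
  out <- list()
  ac_res <- unique(ac[, c("chain", "resno")])
  ba_res <- unique(ba[, c("chain", "resno")])
  bxyz <- model_coords(ba)
  for (i in seq_len(nrow(ac_res))) {
    ai <- which(ac$chain == ac_res$chain[i] & ac$resno == ac_res$resno[i])
    axyz <- model_coords(ac)[ai, , drop = FALSE]
    for (j in seq_len(nrow(ba_res))) {
      if (inter_chain_only && ac_res$chain[i] == ba_res$chain[j]) next
      bj <- which(ba$chain == ba_res$chain[j] & ba$resno == ba_res$resno[j])
      bxyzj <- bxyz[bj, , drop = FALSE]
      dm <- sqrt(pmax(outer(rowSums(axyz^2), rowSums(bxyzj^2), "+") -
                        2 * axyz %*% t(bxyzj), 0))
      k <- arrayInd(which.min(dm), dim(dm))
      dmin <- dm[k]
      if (dmin < cutoff)
        out[[length(out) + 1]] <- data.frame(
          chain_a = ac_res$chain[i], resno_a = ac_res$resno[i],
          resname_a = ac$resname[ai[1]], atom_a = ac$atom[ai[k[1]]],
          chain_b = ba_res$chain[j], resno_b = ba_res$resno[j],
          resname_b = ba$resname[bj[1]], atom_b = ba$atom[bj[k[2]]],
          distance = dmin, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Contact specification
#'
#' Names two atoms (or symmetry-equivalent atom sets, e.g. both Glu
#' carboxylate oxygens) whose separation is to be measured. With mode
#' "min-over-equivalents" the minimum over all atom-name combinations is
#' reported; "specific" requires single atom names.
#'
#' @param chain_a,resno_a,atoms_a first atom reference (atoms_a may list
#'   equivalent names).
#' @param chain_b,resno_b,atoms_b second atom reference.
#' @param mode "min" (min-over-equivalents) or "specific".
#' @return an object of class `ContactSpec`.
#' @export
contact_spec <- function(chain_a, resno_a, atoms_a, chain_b, resno_b, atoms_b,
                         mode = c("min", "specific")) {
  mode <- match.arg(mode)
  if (mode == "specific" && (length(atoms_a) != 1 || length(atoms_b) != 1))
    hf_error("specific mode requires single atom names")
  structure(list(chain_a = chain_a, resno_a = as.integer(resno_a),
                 atoms_a = atoms_a, chain_b = chain_b,
                 resno_b = as.integer(resno_b), atoms_b = atoms_b,
                 mode = mode), class = "ContactSpec")
}

#' Distance for a contact specification
#'
#' Euclidean distance between the two referenced atoms; in min mode the
#' minimum over the listed equivalent atom names on both sides. Unresolvable
#' references raise an error naming the missing atom.
#'
#' @param model an [atomic_model()].
#' @param spec a [contact_spec()].
#' @return distance in Angstrom.
#' @export
interface_distance <- function(model, spec) {
  ia <- atom_index(model, spec$chain_a, spec$resno_a, spec$atoms_a)
  ib <- atom_index(model, spec$chain_b, spec$resno_b, spec$atoms_b)
  pa <- model_coords(model)[ia, , drop = FALSE]
  pb <- model_coords(model)[ib, , drop = FALSE]
  dm <- sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                    2 * pa %*% t(pb), 0))
  min(dm)
}

#' Contact distance changes between straight and bent filaments
#'
#' Evaluates a contact specification across the listed inter-subunit
#' interfaces (the user labels each interface inner or outer with respect to
#' the bending curve) in a straight and a bent filament, and tabulates the
#' change. In bent actin filaments the E167-K61 distance increases on the
#' outside of the bending curve while the inside barely changes.
#'
#' @param straight,bent filament `AtomicModel`s with matching chains.
#' @param spec a [contact_spec()]; its chain fields are overridden per
#'   interface.
#' @param interfaces data.frame with columns `chain_a`, `chain_b`, `label`
#'   (e.g. "inner"/"outer").
#' @return data.frame: label, chain_a, chain_b, straight, bent, delta
#'   (Angstrom).
#' @export
bending_distance_change <- function(straight, bent, spec, interfaces) {
  stopifnot(all(c("chain_a", "chain_b", "label") %in% names(interfaces)))
  rows <- lapply(seq_len(nrow(interfaces)), function(i) {
    sp <- spec
    sp$chain_a <- interfaces$chain_a[i]
    sp$chain_b <- interfaces$chain_b[i]
    ds <- interface_distance(straight, sp)
    db <- interface_distance(bent, sp)
    data.frame(label = interfaces$label[i], chain_a = sp$chain_a,
               chain_b = sp$chain_b, straight = ds, bent = db,
               delta = db - ds, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
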