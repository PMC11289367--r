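#' Read an atomic model from PDB or mmCIF
#'
#' Parses ATOM and HETATM records (PDB v3.3 fixed columns) or the
#' `_atom_site` loop of an mmCIF file. HETATM records (ions, waters, ligands)
#' are retained with their element field populated; chain and residue order
#' follow the file. Only the first model of a multi-MODEL PDB file is read.
#'
#' @param path file path.
#' @param format one of "auto" (by extension), "pdb", "mmcif".
#' @return an [atomic_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) hf_error(sprintf("cannot read model file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  mdl <- if (format == "pdb") parse_pdb_lines(lines) else parse_cif_lines(lines)
  if (is.null(mdl) || nrow(mdl) == 0)
    hf_error(sprintf("no atoms parsed from %s", path))
  as_atomic_model(mdl)
}

parse_pdb_lines <- function(lines) {
  end <- grep("^ENDMDL", lines)
  if (length(end)) lines <- lines[seq_len(end[1] - 1)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec)) return(NULL)
  fx <- function(a, b) substr(rec, a, b)
  element <- trimws(fx(77, 78))
  atom <- trimws(fx(13, 16))
  element <- ifelse(element == "", guess_element(atom), element)
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  b <- suppressWarnings(as.numeric(fx(61, 66)))
  data.frame(chain = trimws(fx(22, 22)),
             resno = as.integer(fx(23, 26)),
             resname = trimws(fx(18, 20)),
             atom = atom,
             element = toupper(element),
             x = as.numeric(fx(31, 38)),
             y = as.numeric(fx(39, 46)),
             z = as.numeric(fx(47, 54)),
             b = ifelse(is.na(b), 0, b),
             occ = ifelse(is.na(occ), 1, occ),
             het = fx(1, 6) == "HETATM",
             stringsAsFactors = FALSE)
}

parse_cif_lines <- function(lines) {
  lines <- trimws(lines)
  istart <- which(lines == "loop_")
  for (s in istart) {
    # collect the tag block directly after loop_
    j <- s + 1
    tags <- character()
    while (j <= length(lines) && startsWith(lines[j], "_")) {
      tags <- c(tags, lines[j]); j <- j + 1
    }
    if (!length(tags) || !all(startsWith(tags, "_atom_site."))) next
    tags <- sub("^_atom_site\\.", "", tags)
    rows <- list()
    while (j <= length(lines) && nzchar(lines[j]) &&
           !startsWith(lines[j], "_") && !startsWith(lines[j], "loop_") &&
           !startsWith(lines[j], "#")) {
      rows[[length(rows) + 1]] <- scan(text = lines[j], what = "character",
                                       quiet = TRUE)
      j <- j + 1
    }
    if (!length(rows)) next
    m <- do.call(rbind, rows)
    colnames(m) <- tags
    col <- function(nm, alt = NULL) {
      if (nm %in% tags) m[, nm]
      else if (!is.null(alt) && alt %in% tags) m[, alt]
      else NULL
    }
    chain <- col("auth_asym_id", "label_asym_id")
    resno <- col("auth_seq_id", "label_seq_id")
    num <- function(v, default) {
      v <- suppressWarnings(as.numeric(v))
      ifelse(is.na(v), default, v)
    }
    return(data.frame(
      chain = as.character(chain),
      resno = as.integer(resno),
      resname = as.character(col("auth_comp_id", "label_comp_id")),
      atom = gsub('"', "", as.character(col("auth_atom_id", "label_atom_id"))),
      element = toupper(as.character(col("type_symbol"))),
      x = as.numeric(m[, "Cartn_x"]),
      y = as.numeric(m[, "Cartn_y"]),
      z = as.numeric(m[, "Cartn_z"]),
      b = num(col("B_iso_or_equiv"), 0),
      occ = num(col("occupancy"), 1),
      het = as.character(col("group_PDB")) == "HETATM",
      stringsAsFactors = FALSE))
  }
  NULL
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB output uses v3.3 fixed columns (coordinates to 0.001 Angstrom,
#' occupancy/B to 2 decimals). Residue numbers above 9999 or multi-character
#' chain ids do not fit the PDB format and raise an error unless
#' `fallback_mmcif = TRUE`, in which case an mmCIF file is written instead.
#'
#' @param model an [atomic_model()].
#' @param path output file path.
#' @param format "pdb" or "mmcif".
#' @param fallback_mmcif write mmCIF (with a warning) when the model does not
#'   fit PDB fixed columns.
#' @return invisibly, the path written.
#' @export
write_model <- function(model, path, format = c("pdb", "mmcif"),
                        fallback_mmcif = FALSE) {
  format <- match.arg(format)
  validate_atomic_model(model)
  if (format == "pdb") {
    bad <- any(model$resno > 9999L) || any(nchar(model$chain) > 1L)
    if (bad) {
      if (!fallback_mmcif)
        hf_error("model does not fit PDB fixed columns (resno > 9999 or multi-char chain); use mmCIF")
      warning("falling back to mmCIF format")
      format <- "mmcif"
    }
  }
  lines <- if (format == "pdb") format_pdb(model) else format_cif(model)
  writeLines(lines, path)
  invisible(path)
}

format_pdb <- function(model) {
  n <- nrow(model)
  name <- model$atom
  # column-13 convention: single-letter elements start in column 14
  name4 <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
                  ifelse(nchar(model$element) == 1,
                         sprintf(" %-3s", name), sprintf("%-4s", name)))
  rec <- ifelse(model$het, "HETATM", "ATOM  ")
  c(sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, pmin(seq_len(n), 99999L), name4, model$resname, model$chain,
            model$resno, model$x, model$y, model$z, model$occ, model$b,
            formatC(model$element, width = 2)),
    "END")
}

format_cif <- function(model) {
  c("data_helixforge",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    sprintf("%s %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f",
            ifelse(model$het, "HETATM", "ATOM"), seq_len(nrow(model)),
            model$element, model$atom, model$resname, model$chain,
            model$resno, model$x, model$y, model$z, model$occ, model$b),
    "#")
}
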