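#' Atomic model container
#'
#' An `AtomicModel` is an ordered atom table (a `data.frame` subclass) with one
#' row per atom and columns `chain`, `resno`, `resname`, `atom`, `element`,
#' `x`, `y`, `z`, `b` (isotropic B-factor, Angstrom^2), `occ` (occupancy) and
#' `het` (logical, HETATM flag). Chain/residue order is the file (or
#' construction) order and is preserved by all operations. The
#' (chain, resno, atom) triple must be unique.
#'
#' @param chain character chain identifiers.
#' @param resno integer residue numbers.
#' @param resname 3-letter residue names.
#' @param atom atom names (PDB conventions, e.g. "CA", "OE1").
#' @param element element symbols ("C", "N", "O", "MG", ...).
#' @param x,y,z coordinates in Angstrom.
#' @param b isotropic B-factors in Angstrom^2 (>= 0).
#' @param occ occupancies in [0, 1].
#' @param het logical HETATM flags.
#' @return an object of class `AtomicModel`.
#' @examples
#' m <- atomic_model(chain = "A", resno = 1L, resname = "GLY", atom = "CA",
#'                   element = "C", x = 0, y = 0, z = 0)
#' @export
atomic_model <- function(chain, resno, resname, atom, element, x, y, z,
                         b = 0, occ = 1, het = FALSE) {
  df <- data.frame(chain = as.character(chain),
                   resno = as.integer(resno),
                   resname = as.character(resname),
                   atom = as.character(atom),
                   element = toupper(as.character(element)),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   b = as.numeric(b), occ = as.numeric(occ),
                   het = as.logical(het),
                   stringsAsFactors = FALSE)
  validate_atomic_model(df)
  class(df) <- c("AtomicModel", "data.frame")
  df
}

validate_atomic_model <- function(df) {
  if (nrow(df) == 0) hf_error("empty model: no atoms")
  if (!all(is.finite(c(df$x, df$y, df$z))))
    hf_error("non-finite coordinates in model")
  if (any(df$b < 0)) hf_error("negative B-factor")
  if (any(df$occ < 0 | df$occ > 1)) hf_error("occupancy outside [0, 1]")
  key <- paste(df$chain, df$resno, df$atom, sep = "\r")
  if (anyDuplicated(key))
    hf_error("duplicate (chain, residue, atom) triple in model")
  invisible(df)
}

as_atomic_model <- function(df) {
  validate_atomic_model(df)
  if (!inherits(df, "AtomicModel")) class(df) <- c("AtomicModel", "data.frame")
  df
}

#' @export
print.AtomicModel <- function(x, ...) {
  cat(sprintf("<AtomicModel> %d atoms, %d chains (%s), residues %d..%d\n",
              nrow(x), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ","),
              min(x$resno), max(x$resno)))
  invisible(x)
}

#' Coordinates of a model as a matrix
#'
#' @param model an `AtomicModel`.
#' @return an n x 3 numeric matrix of coordinates (Angstrom).
#' @export
model_coords <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

set_model_coords <- function(model, xyz) {
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Apply a rigid transform to a model
#'
#' Applies `x -> R x + t` to every atom.
#'
#' @param model an `AtomicModel`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (Angstrom).
#' @return the transformed `AtomicModel`.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  set_model_coords(model, apply_rigid(model_coords(model), R, t))
}

# Row subset keeping the class.
model_subset <- function(model, idx) {
  out <- model[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("AtomicModel", "data.frame")
  out
}

# Single-atom lookup; errors with a readable reference when absent and
# strict = TRUE, otherwise returns integer(0).
atom_index <- function(model, chain, resno, atom, strict = TRUE) {
  idx <- which(model$chain == chain & model$resno == resno &
                 model$atom %in% atom)
  if (strict && length(idx) == 0)
    hf_error(sprintf("atom not found: %s/%s/%s", chain, resno,
                     paste(atom, collapse = ",")))
  idx
}

ca_subset <- function(model) model_subset(model, which(model$atom == "CA"))

# Guess an element from a PDB atom name when columns 77-78 are blank.
guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("MG", "FE", "ZN", "NA", "CL", "MN", "CA")
  ifelse(two %in% known2 & nchar(nm) == nchar(two), two,
         toupper(substr(nm, 1, 1)))
}

# Approximate atomic numbers for the Gaussian atom model.
element_z <- function(element) {
  tab <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, MG = 12, NA. = 11,
           K = 19, CL = 17, CA = 20, MN = 25, FE = 26, ZN = 30, BE = 4, F = 9)
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  z <- tab[key]
  z[is.na(z)] <- 6  # unknown elements score like carbon
  unname(z)
}
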