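# Uniform in-memory representation of a macromolecular structure.
#
# A StructureModel is a list with
#   $metadata : list(entry_id, method, resolution, model_count)
#   $atoms    : data.frame with one row per atom, file order preserved:
#               type ("ATOM"/"HETATM"), eleno, name, altloc, resname, chain,
#               resno (author numbering), icode, x, y, z, occ, b, element,
#               is_polymer, is_water
# Author residue numbers (plus insertion codes) are the public coordinate
# system; row order is the only internal index and is never exposed.

.stop_data <- function(msg, ...) {
  stop(structure(class = c("insertag_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

.stop_usage <- function(msg, ...) {
  stop(structure(class = c("insertag_usage_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

.atom_cols <- c("type", "eleno", "name", "altloc", "resname", "chain",
                "resno", "icode", "x", "y", "z", "occ", "b", "element",
                "is_polymer", "is_water")

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by the readers and the fixture generator.
#' Most users obtain models via [read_structure()] or the `make_*` fixture
#' functions.
#'
#' @param atoms data.frame with columns `type`, `eleno`, `name`, `altloc`,
#'   `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`, `b`,
#'   `element` (classification columns `is_polymer`/`is_water` are derived
#'   when absent).
#' @param entry_id entry identifier string.
#' @param method experimental method string (e.g. "X-RAY DIFFRACTION").
#' @param resolution resolution in Angstrom, or `NA` when unknown.
#' @param model_count number of models in the source file (only the first is
#'   kept in the atom table).
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(atoms, entry_id = "XXXX",
                            method = "X-RAY DIFFRACTION",
                            resolution = NA_real_, model_count = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$is_water <- atoms$resname %in% .water_codes
  if (is.null(atoms$is_polymer) || all(is.na(atoms$is_polymer))) {
    atoms$is_polymer <- (atoms$type == "ATOM" |
                           atoms$resname %in% names(.aa3to1)) &
      !atoms$is_water
  }
  atoms$is_polymer <- atoms$is_polymer & !atoms$is_water
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    .stop_data("non-finite coordinates at atom serial %s",
               paste(atoms$eleno[bad], collapse = ","))
  }
  if (!is.na(resolution) && resolution <= 0) {
    .stop_data("resolution must be positive, got %s", resolution)
  }
  atoms <- atoms[, .atom_cols]
  rownames(atoms) <- NULL
  structure(list(
    metadata = list(entry_id = entry_id, method = method,
                    resolution = resolution,
                    model_count = as.integer(model_count)),
    atoms = atoms
  ), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("StructureModel %s  [%s%s]\n", m$entry_id, m$method,
              if (is.na(m$resolution)) "" else
                sprintf(", %.2f A", m$resolution)))
  cat(sprintf("  chains: %s\n", paste(chain_ids(x), collapse = " ")))
  cat(sprintf("  %d atoms (%d polymer, %d het, %d water)\n",
              nrow(x$atoms), sum(x$atoms$is_polymer),
              sum(!x$atoms$is_polymer & !x$atoms$is_water),
              sum(x$atoms$is_water)))
  invisible(x)
}

#' Chain identifiers of a structure model
#'
#' @param model a `StructureModel`.
#' @param polymer_only if `TRUE`, only chains with at least one polymer
#'   residue are listed.
#' @return character vector of chain ids in file order.
#' @export
chain_ids <- function(model, polymer_only = FALSE) {
  a <- model$atoms
  if (polymer_only) a <- a[a$is_polymer, , drop = FALSE]
  unique(a$chain)
}

#' Extract one chain from a structure model
#'
#' @param model a `StructureModel`.
#' @param chain_id chain identifier.
#' @return an object of class `Chain`: a list with `chain_id` and the
#'   chain's `atoms` table (file order preserved).
#' @export
get_chain <- function(model, chain_id) {
  a <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0) .stop_data("no chain '%s' in model", chain_id)
  rownames(a) <- NULL
  structure(list(chain_id = chain_id, atoms = a), class = "Chain")
}

#' @export
print.Chain <- function(x, ...) {
  rt <- residue_table(x$atoms)
  cat(sprintf("Chain %s: %d polymer residues, %d het residues\n",
              x$chain_id, sum(rt$is_polymer & !rt$is_water),
              sum(!rt$is_polymer & !rt$is_water)))
  invisible(x)
}

# One row per residue, in file order.  key is chain|resno|icode.
residue_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  first <- !duplicated(key)
  data.frame(key = key[first], chain = atoms$chain[first],
             resno = atoms$resno[first], icode = atoms$icode[first],
             resname = atoms$resname[first],
             is_polymer = atoms$is_polymer[first],
             is_water = atoms$is_water[first],
             stringsAsFactors = FALSE)
}

.residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$icode,
                                      sep = "|")

#' Resolve alternate locations
#'
#' Collapses alternate-location atoms so each atom name occurs once per
#' residue.  Under the `highest_occupancy` policy the altloc with the
#' largest occupancy wins; ties are broken by altloc character order (so 'A'
#' beats 'B' at equal occupancy).  Atoms without an altloc are untouched.
#'
#' @param model a `StructureModel`.
#' @param policy currently only `"highest_occupancy"`.
#' @return the model with exactly one location per atom name per residue.
#' @export
resolve_altlocs <- function(model, policy = "highest_occupancy") {
  policy <- match.arg(policy, "highest_occupancy")
  a <- model$atoms
  alt <- a$altloc != ""
  if (!any(alt)) return(model)
  key <- paste(.residue_key(a), a$name, sep = "|")
  # order: prefer higher occupancy, then earlier altloc character
  ord <- order(key, -a$occ, a$altloc)
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  model$atoms <- a[keep, , drop = FALSE]
  model$atoms$altloc <- ""
  rownames(model$atoms) <- NULL
  model
}

#' One-letter sequence of a chain's polymer residues
#'
#' Non-standard residues with a known parent (MSE, SEP, ...) map to the
#' parent's one-letter code; unknown polymer residues become 'X'.
#'
#' @param chain a `Chain` (from [get_chain()]) or a `StructureModel` plus
#'   `chain_id`.
#' @param chain_id chain identifier when `chain` is a model.
#' @return one-letter amino-acid string, one letter per polymer residue.
#' @export
polymer_sequence <- function(chain, chain_id = NULL) {
  if (inherits(chain, "StructureModel")) chain <- get_chain(chain, chain_id)
  rt <- residue_table(chain$atoms)
  rt <- rt[rt$is_polymer, , drop = FALSE]
  if (nrow(rt) == 0) .stop_data("chain '%s' has no polymer residues",
                                chain$chain_id)
  nuc <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")
  if (mean(rt$resname %in% nuc) > 0.5) {
    .stop_data("chain '%s' looks like a nucleic-acid polymer; only protein chains are supported",
               chain$chain_id)
  }
  letters1 <- .aa3to1[rt$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

# Coordinates of a named atom per polymer residue of a chain, in residue
# order; rows of NA where the residue lacks that atom.
.residue_atom_xyz <- function(chain, atom_name = "CA") {
  a <- chain$atoms[chain$atoms$is_polymer, , drop = FALSE]
  rt <- residue_table(a)
  sel <- a[a$name == atom_name, , drop = FALSE]
  idx <- match(rt$key, .residue_key(sel))
  cbind(x = sel$x[idx], y = sel$y[idx], z = sel$z[idx])
}
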