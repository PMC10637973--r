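# Reading PDB/mmCIF coordinate files into a StructureModel and writing
# minimal PDB for fixtures and round-trips.
#
# Atom records are parsed by bio3d (read.pdb / read.cif); header metadata
# (method, resolution, entry id) is extracted here because bio3d does not
# surface it.  When refinement and REMARK 2 resolutions disagree the
# refinement value wins, REMARK 2 is the fallback.

#' Read a structure file
#'
#' Reads a PDB or mmCIF file into a [structure_model()].  Only the first
#' model of a multi-model file is retained (crystallographic use case).
#' Waters are classified as het residues, separate from ligands.
#'
#' @param path path to a coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect by extension, then
#'   content sniffing).
#' @return a `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stop_data("file not found: %s", path)
  if (format == "auto") format <- .detect_format(path)
  parsed <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) .stop_data("cannot parse %s file '%s': %s",
                                   format, path, conditionMessage(e)))
  at <- parsed$atom
  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  element <- ifelse(is.na(element) | trimws(element) == "",
                    .guess_element(at$elety), trimws(element))
  atoms <- data.frame(
    type = at$type, eleno = at$eleno, name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    element = toupper(element), stringsAsFactors = FALSE)
  meta <- if (format == "pdb") .pdb_metadata(path) else .cif_metadata(path)
  model <- structure_model(atoms, entry_id = meta$entry_id,
                           method = meta$method,
                           resolution = meta$resolution,
                           model_count = meta$model_count)
  if (!any(model$atoms$is_polymer)) {
    .stop_data("'%s' contains no polymer residues", path)
  }
  model
}

.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  head_lines <- readLines(path, n = 50, warn = FALSE)
  if (any(grepl("^(data_|_atom_site\\.|loop_)", head_lines))) return("mmcif")
  if (any(grepl("^(ATOM  |HETATM|HEADER|REMARK)", head_lines))) return("pdb")
  .stop_data("cannot detect format of '%s'", path)
}

.guess_element <- function(name) {
  n <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(n, 1, 2))
  one <- toupper(substr(n, 1, 1))
  ifelse(two %in% names(.vdw_radii) & !(one %in% c("C", "N", "O", "S", "P", "H")),
         two, one)
}

.pdb_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entry_id <- "XXXX"
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr)) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(id)) entry_id <- id
  }
  method <- NA_character_
  exp <- grep("^EXPDTA", lines, value = TRUE)
  if (length(exp)) method <- trimws(substr(exp[1], 11, 79))
  resolution <- NA_real_
  # refinement record first, then REMARK 2
  r3 <- grep("^REMARK   3   RESOLUTION RANGE HIGH", lines, value = TRUE)
  if (length(r3)) {
    resolution <- suppressWarnings(as.numeric(sub(".*:", "", r3[1])))
  }
  if (is.na(resolution)) {
    r2 <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(r2)) {
      rest <- sub(".*RESOLUTION\\.", "", r2[1])
      m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
      if (length(m) && nzchar(m)) resolution <- as.numeric(m)
    }
  }
  model_count <- max(1L, sum(grepl("^MODEL ", lines)))
  list(entry_id = entry_id, method = method, resolution = resolution,
       model_count = model_count)
}

.cif_value <- function(lines, tag) {
  hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  val <- trimws(sub(paste0("^", tag, "\\s+"), "", hit[1]))
  gsub("^['\"]|['\"]$", "", val)
}

.cif_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entry_id <- .cif_value(lines, "_entry\\.id")
  if (is.na(entry_id)) {
    d <- grep("^data_", lines, value = TRUE)
    entry_id <- if (length(d)) sub("^data_", "", d[1]) else "XXXX"
  }
  method <- .cif_value(lines, "_exptl\\.method")
  res <- suppressWarnings(as.numeric(.cif_value(lines, "_refine\\.ls_d_res_high")))
  if (is.na(res)) {
    res <- suppressWarnings(as.numeric(.cif_value(lines, "_reflns\\.d_resolution_high")))
  }
  list(entry_id = entry_id, method = method, resolution = res,
       model_count = 1L)
}

#' Write a structure model as a minimal PDB file
#'
#' Emits HEADER/EXPDTA/REMARK 2 metadata followed by fixed-column
#' ATOM/HETATM records; the output re-reads with [read_structure()] to the
#' same chain/residue/atom counts and coordinates.  Output is
#' byte-deterministic for a given model.
#'
#' @param model a `StructureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  m <- model$metadata
  lines <- character(0)
  lines <- c(lines, sprintf("%-62s%4s", "HEADER    SYNTHETIC STRUCTURE",
                            m$entry_id))
  if (!is.na(m$method)) lines <- c(lines, sprintf("EXPDTA    %s", m$method))
  if (!is.na(m$resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                              m$resolution))
  }
  a <- model$atoms
  name_fmt <- ifelse(nchar(a$name) >= 4, a$name,
                     formatC(paste0(" ", a$name), width = -4))
  rec <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 a$type, a$eleno %% 100000L, name_fmt,
                 substr(paste0(a$altloc, " "), 1, 1),
                 a$resname, a$chain, a$resno %% 10000L,
                 substr(paste0(a$icode, " "), 1, 1),
                 a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, rec, "END"), path)
  invisible(path)
}
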