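# Fusion-construct assembly with segment provenance, author-numbered point
# mutations, and the geometric tag/anchor compatibility check.

.check_aa <- function(sequence, what = "sequence") {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), .aa_alphabet)
  if (length(bad)) .stop_data("%s contains non-amino-acid characters: %s",
                              what, paste(bad, collapse = ""))
  invisible(sequence)
}

#' Tag specification
#'
#' Describes an insertion tag: its sequence over an author-numbered residue
#' range, the spatial separation of its terminal C-alpha atoms, and point
#' mutations to apply (e.g. surface-entropy-reduction substitutions).
#'
#' @param sequence one-letter tag sequence (covering `range_start:range_end`).
#' @param range_start,range_end author residue numbers of the first/last tag
#'   residue used (e.g. 3 and 123 for a tag trimmed to residues 3-123).
#' @param termini_ca_distance separation of the tag's terminal C-alpha atoms
#'   in Angstrom (`NA` when no structure is at hand).
#' @param mutations character vector of point mutations, `"X<pos>Y"` in the
#'   tag's author numbering; applied by [build_fusion()].
#' @param name label used in provenance records.
#' @return object of class `TagSpec`.
#' @export
tag_spec <- function(sequence, range_start = 1,
                     range_end = range_start + nchar(sequence) - 1,
                     termini_ca_distance = NA_real_,
                     mutations = character(0), name = "tag") {
  .check_aa(sequence, "tag sequence")
  if (range_end - range_start + 1 != nchar(sequence)) {
    .stop_data("tag range %d-%d does not match sequence length %d",
               range_start, range_end, nchar(sequence))
  }
  for (m in mutations) .parse_mutation(m, range_start, range_end)
  structure(list(sequence = sequence, range_start = range_start,
                 range_end = range_end,
                 termini_ca_distance = termini_ca_distance,
                 mutations = mutations, name = name), class = "TagSpec")
}

#' Insertion specification
#'
#' Describes where a tag replaces an internal segment of the target: the
#' last retained residue on the N side (`n_anchor`) and the first retained
#' residue on the C side (`c_anchor`), in the target's author numbering.
#' Residues strictly between the anchors are removed.
#'
#' @param target_sequence one-letter target sequence.
#' @param offset author residue number of the first letter of
#'   `target_sequence` (UniProt-isoform numbering is the usual convention).
#' @param n_anchor,c_anchor author residue numbers of the anchors;
#'   `n_anchor < c_anchor`.
#' @param linker_n,linker_c optional linker sequences placed before/after
#'   the tag.
#' @param name label used in provenance records.
#' @return object of class `InsertionSpec`.
#' @export
insertion_spec <- function(target_sequence, offset = 1, n_anchor, c_anchor,
                           linker_n = "", linker_c = "", name = "target") {
  .check_aa(target_sequence, "target sequence")
  if (nzchar(linker_n)) .check_aa(linker_n, "N-side linker")
  if (nzchar(linker_c)) .check_aa(linker_c, "C-side linker")
  last <- offset + nchar(target_sequence) - 1
  if (!(n_anchor >= offset && n_anchor <= last) ||
      !(c_anchor >= offset && c_anchor <= last)) {
    .stop_data("anchors %d/%d outside target range %d-%d", n_anchor,
               c_anchor, offset, last)
  }
  if (n_anchor >= c_anchor) .stop_data("n_anchor (%d) must precede c_anchor (%d)",
                                       n_anchor, c_anchor)
  structure(list(target_sequence = target_sequence, offset = offset,
                 n_anchor = n_anchor, c_anchor = c_anchor,
                 linker_n = linker_n, linker_c = linker_c, name = name),
            class = "InsertionSpec")
}

#' C-alpha distance between two anchor residues
#'
#' @param model a `StructureModel` of the target.
#' @param chain_id chain identifier.
#' @param n_anchor,c_anchor author residue numbers of the anchors.
#' @return Euclidean C-alpha to C-alpha distance in Angstrom.
#' @export
anchor_distance <- function(model, chain_id, n_anchor, c_anchor) {
  a <- model$atoms
  pick <- function(res) {
    hit <- a[a$chain == chain_id & a$resno == res & a$name == "CA" &
               a$is_polymer, , drop = FALSE]
    if (nrow(hit) == 0) .stop_data("anchor residue %s/%d has no resolved C-alpha",
                                   chain_id, res)
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  sqrt(sum((pick(n_anchor) - pick(c_anchor))^2))
}

#' Tag/anchor geometric compatibility
#'
#' A tag fits an insertion site when the mismatch between the anchor
#' C-alpha distance and the tag's own termini separation can be absorbed by
#' the base tolerance plus linker reach, modeled as 3.5 A per linker residue
#' (near-extended backbone):
#' `pass` iff `|anchor_d - tag_termini_d| <= tolerance + 3.5 * linker_residues`.
#'
#' @param anchor_d anchor C-alpha distance (Angstrom).
#' @param tag_termini_d tag termini C-alpha distance (Angstrom).
#' @param tolerance base tolerance in Angstrom (default 4.0).
#' @param linker_residues total residues in N- plus C-side linkers.
#' @return list with `pass`, `mismatch`, `allowed` and `slack`
#'   (= allowed - mismatch, in Angstrom; negative when incompatible).
#' @export
compatibility <- function(anchor_d, tag_termini_d, tolerance = 4.0,
                          linker_residues = 0) {
  if (anchor_d < 0 || tag_termini_d < 0) .stop_usage("distances must be >= 0")
  mismatch <- abs(anchor_d - tag_termini_d)
  allowed <- tolerance + 3.5 * linker_residues
  list(pass = mismatch <= allowed, mismatch = mismatch, allowed = allowed,
       slack = allowed - mismatch)
}

.parse_mutation <- function(m, range_start = NULL, range_end = NULL) {
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", m)
  if (!ok) .stop_data("malformed mutation '%s' (expected e.g. K94A)", m)
  pos <- as.integer(gsub("[A-Z]", "", m))
  out <- list(from = substr(m, 1, 1), pos = pos,
              to = substr(m, nchar(m), nchar(m)))
  if (!is.null(range_start) && (pos < range_start || pos > range_end)) {
    .stop_data("mutation '%s' outside residue range %d-%d", m, range_start,
               range_end)
  }
  out
}

#' Apply author-numbered point mutations to a sequence
#'
#' Each mutation `"X<pos>Y"` is validated against the sequence: the
#' wild-type letter `X` must match the sequence at author position `pos`
#' (position `pos - numbering_offset + 1` in the string), which guards
#' against off-by-one numbering mistakes.
#'
#' @param sequence one-letter sequence.
#' @param numbering_offset author residue number of the first letter.
#' @param mutations character vector like `c("K94A", "K96S")`.
#' @return mutated sequence with attribute `mutation_log`, a data.frame of
#'   `mutation`, `position`, `from`, `to`.
#' @export
apply_point_mutations <- function(sequence, numbering_offset = 1,
                                  mutations = character(0)) {
  aa <- strsplit(sequence, "")[[1]]
  log <- data.frame(mutation = character(0), position = integer(0),
                    from = character(0), to = character(0),
                    stringsAsFactors = FALSE)
  for (m in mutations) {
    mu <- .parse_mutation(m)
    i <- mu$pos - numbering_offset + 1
    if (i < 1 || i > length(aa)) .stop_data("mutation '%s' outside sequence (positions %d-%d)",
                                            m, numbering_offset,
                                            numbering_offset + length(aa) - 1)
    if (aa[i] != mu$from) {
      .stop_data("mutation '%s': expected %s at position %d but sequence has %s",
                 m, mu$from, mu$pos, aa[i])
    }
    aa[i] <- mu$to
    log <- rbind(log, data.frame(mutation = m, position = mu$pos,
                                 from = mu$from, to = mu$to,
                                 stringsAsFactors = FALSE))
  }
  structure(paste(aa, collapse = ""), mutation_log = log)
}

.fusion_from_segments <- function(segments, mutation_log = NULL,
                                  notes = character(0)) {
  segments <- segments[segments$length > 0, , drop = FALSE]
  sequence <- paste(segments$sequence, collapse = "")
  rownames(segments) <- NULL
  structure(list(sequence = sequence, segments = segments,
                 length = nchar(sequence), mw = peptide_mw(sequence),
                 mutation_log = mutation_log, notes = notes),
            class = "FusionConstruct")
}

#' @export
print.FusionConstruct <- function(x, ...) {
  cat(sprintf("FusionConstruct: %d residues, %.1f Da, %d segments\n",
              x$length, x$mw, nrow(x$segments)))
  for (k in seq_len(nrow(x$segments))) {
    s <- x$segments[k, ]
    cat(sprintf("  %-12s %5d-%-5d (%d aa)\n", s$source, s$start, s$end,
                s$length))
  }
  if (!is.null(x$mutation_log) && nrow(x$mutation_log)) {
    cat("  mutations:", paste(x$mutation_log$mutation, collapse = ", "), "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Build a loop-insertion fusion construct
#'
#' Assembles target N-part (first residue through `n_anchor`), optional
#' N-side linker, tag (with its point mutations applied), optional C-side
#' linker, and target C-part (`c_anchor` through the last residue), tracking
#' each segment's source and author-numbered range.  The length of the
#' removed target segment (residues strictly between the anchors) is
#' recorded in the notes.
#'
#' @param spec an `InsertionSpec`.
#' @param tag a `TagSpec`, a plain linker sequence string (e.g. `"ASTSK"`),
#'   or `""` for a direct junction.
#' @return a `FusionConstruct`: final sequence, segment provenance table,
#'   length, molecular weight, mutation log and notes.  Length conservation
#'   (final length = sum of segment lengths, concatenation of segments =
#'   sequence) holds by construction and is asserted.
#' @export
build_fusion <- function(spec, tag = "") {
  stopifnot(inherits(spec, "InsertionSpec"))
  sub_target <- function(from, to) {
    substr(spec$target_sequence, from - spec$offset + 1,
           to - spec$offset + 1)
  }
  last <- spec$offset + nchar(spec$target_sequence) - 1
  mut_log <- NULL
  if (inherits(tag, "TagSpec")) {
    tag_seq <- apply_point_mutations(tag$sequence, tag$range_start,
                                     tag$mutations)
    mut_log <- attr(tag_seq, "mutation_log")
    tag_row <- data.frame(source = tag$name, start = tag$range_start,
                          end = tag$range_end, length = nchar(tag_seq),
                          sequence = as.character(tag_seq),
                          stringsAsFactors = FALSE)
  } else {
    .check_aa(tag, "tag/linker sequence")
    tag_row <- data.frame(source = "linker", start = 1L,
                          end = nchar(tag), length = nchar(tag),
                          sequence = tag, stringsAsFactors = FALSE)
  }
  seg <- rbind(
    data.frame(source = spec$name, start = spec$offset, end = spec$n_anchor,
               length = spec$n_anchor - spec$offset + 1,
               sequence = sub_target(spec$offset, spec$n_anchor),
               stringsAsFactors = FALSE),
    data.frame(source = "linker_n", start = 1L, end = nchar(spec$linker_n),
               length = nchar(spec$linker_n), sequence = spec$linker_n,
               stringsAsFactors = FALSE),
    tag_row,
    data.frame(source = "linker_c", start = 1L, end = nchar(spec$linker_c),
               length = nchar(spec$linker_c), sequence = spec$linker_c,
               stringsAsFactors = FALSE),
    data.frame(source = spec$name, start = spec$c_anchor, end = last,
               length = last - spec$c_anchor + 1,
               sequence = sub_target(spec$c_anchor, last),
               stringsAsFactors = FALSE))
  removed <- spec$c_anchor - spec$n_anchor - 1
  notes <- sprintf("replaced %d target residues (%d-%d exclusive of anchors)",
                   removed, spec$n_anchor + 1, spec$c_anchor - 1)
  out <- .fusion_from_segments(seg, mut_log, notes)
  stopifnot(out$length == sum(out$segments$length),
            identical(paste(out$segments$sequence, collapse = ""),
                      out$sequence))
  out
}

#' Extend a sequence at the C terminus
#'
#' Builds substrate variants such as a ubiquitin core extended by extra
#' glycines (the linear mimic of an isopeptide-linked tail).
#'
#' @param base one-letter base sequence.
#' @param extension residues appended at the C terminus (may be `""` for the
#'   identity).
#' @param base_name,extension_name provenance labels.
#' @return a `FusionConstruct` with two provenance segments (one when the
#'   extension is empty).
#' @export
c_terminal_extension <- function(base, extension, base_name = "base",
                                 extension_name = "extension") {
  .check_aa(base, "base sequence")
  if (nzchar(extension)) .check_aa(extension, "extension")
  seg <- rbind(
    data.frame(source = base_name, start = 1L, end = nchar(base),
               length = nchar(base), sequence = base,
               stringsAsFactors = FALSE),
    data.frame(source = extension_name, start = 1L, end = nchar(extension),
               length = nchar(extension), sequence = extension,
               stringsAsFactors = FALSE))
  .fusion_from_segments(seg)
}

#' Write fusion constructs to FASTA
#'
#' @param constructs a `FusionConstruct` or list of them.
#' @param path output file.
#' @param names sequence names (defaults to `construct_1`, ...).
#' @return `path`, invisibly.
#' @export
write_constructs_fasta <- function(constructs, path, names = NULL) {
  if (inherits(constructs, "FusionConstruct")) constructs <- list(constructs)
  if (is.null(names)) names <- paste0("construct_", seq_along(constructs))
  lines <- unlist(lapply(seq_along(constructs), function(i) {
    c(paste0(">", names[i]),
      gsub("(.{60})", "\\1\n", constructs[[i]]$sequence))
  }))
  writeLines(lines, path)
  invisible(path)
}
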