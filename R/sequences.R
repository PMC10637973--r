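# Built-in and synthetic sequences used by the construct-design examples.

#' Human ubiquitin sequence, residues 1-76
#'
#' The canonical 76-residue human ubiquitin sequence.  Substrate variants
#' are built from it with [c_terminal_extension()], e.g. the linear
#' triple-glycine tail mimic of an isopeptide-linked ubiquitin.
#'
#' @return one-letter string of length 76.
#' @export
ubiquitin_sequence <- function() {
  paste0("MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYN",
         "IQKESTLHLVLRLRGG")
}

#' Deterministic synthetic stand-in sequence
#'
#' Generates a reproducible pseudo-random amino-acid sequence for use as a
#' stand-in target or tag when the real sequence is not bundled.  Specific
#' author-numbered positions can be pinned to given residues so that point
#' mutations validate (e.g. lysines at tag positions 94 and 96 for
#' surface-entropy-reduction substitutions).
#'
#' @param n sequence length.
#' @param seed integer seed.
#' @param offset author residue number of the first residue (numbering
#'   metadata only; the returned string has `n` letters).
#' @param pin named character vector: names are author residue numbers,
#'   values one-letter codes to place there (e.g. `c("94" = "K")`).
#' @return one-letter string of length `n`, with attribute `offset`.
#' @export
synthetic_sequence <- function(n, seed = 1, offset = 1, pin = character(0)) {
  aa <- .with_seed(seed, sample(unname(.aa3to1[1:20]), n, replace = TRUE))
  if (length(pin)) {
    pos <- as.integer(names(pin)) - offset + 1
    if (any(pos < 1 | pos > n)) .stop_usage("pinned position outside sequence")
    aa[pos] <- pin
  }
  structure(paste(aa, collapse = ""), offset = offset)
}

#' Synthetic tag sequence with SER-targetable lysines
#'
#' A deterministic 121-residue stand-in for a receiver-domain-sized
#' insertion tag spanning author residues 3-123, with lysines pinned at
#' positions 94 and 96 so the classic surface-entropy-reduction mutations
#' K94A and K96S validate against it.  This is a synthetic sequence, not
#' the real domain.
#'
#' @param seed integer seed.
#' @return a [tag_spec()] covering residues 3-123 with
#'   `termini_ca_distance = 6.3` and mutations `K94A`, `K96S`.
#' @export
synthetic_rd_tag <- function(seed = 1) {
  s <- synthetic_sequence(121, seed = seed, offset = 3,
                          pin = c("94" = "K", "96" = "K"))
  tag_spec(as.character(s), range_start = 3, range_end = 123,
           termini_ca_distance = 6.3, mutations = c("K94A", "K96S"),
           name = "rd_tag_synthetic")
}

#' Synthetic deubiquitinase catalytic-core target
#'
#' A deterministic stand-in for a two-subdomain protease catalytic core
#' spanning author residues 295-937 (643 residues), used to exercise the
#' loop-replacement arithmetic: the flexible insertion between anchor
#' residues 489 and 778 is replaced by a tag or short linker.  This is a
#' synthetic sequence, not the real protein.
#'
#' @param seed integer seed.
#' @return an [insertion_spec()] with offset 295 and anchors 489/778.
#' @export
synthetic_usp_target <- function(seed = 1) {
  s <- synthetic_sequence(643, seed = seed + 7, offset = 295,
                          pin = c("489" = "P", "778" = "P", "318" = "C"))
  insertion_spec(as.character(s), offset = 295, n_anchor = 489,
                 c_anchor = 778, name = "usp_target_synthetic")
}
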