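# Rigid-body superposition (Kabsch), global sequence identity, and
# sequence-guided structure superposition with iterative outlier rejection.

#' Optimal rigid superposition of matched point sets (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1, reflections forbidden) and
#' translation `t` minimizing the RMSD of `R %*% p + t` against `Q`, via the
#' SVD of the cross-covariance matrix.
#'
#' @param P,Q n x 3 matrices of matched coordinates (P is moved onto Q).
#' @param allow_degenerate permit collinear point sets (rotation about the
#'   common axis is then arbitrary but the RMSD is still well defined).
#' @return object of class `SuperpositionResult`: `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_pairs_used`,
#'   `n_pairs_total`.
#' @export
kabsch <- function(P, Q, allow_degenerate = FALSE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3) {
    .stop_usage("P and Q must be matched n x 3 matrices")
  }
  n <- nrow(P)
  if (n < 3) .stop_data("need at least 3 point pairs, got %d", n)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (!allow_degenerate && sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    .stop_data("degenerate (collinear) geometry: rotation is underdetermined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  moved <- t(R %*% t(P)) + matrix(t, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd,
                 n_pairs_used = n, n_pairs_total = n),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd %.3f A over %d of %d pairs\n",
              x$rmsd, x$n_pairs_used, x$n_pairs_total))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param result a `SuperpositionResult`.
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(result, xyz) {
  xyz <- as.matrix(xyz)
  t(result$rotation %*% t(xyz)) +
    matrix(result$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Global pairwise sequence alignment and identity
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open
#' 10, gap extend 0.5 by default, via Biostrings).  Identity is the number
#' of identical aligned pairs over the number of aligned (non-gap) pairs —
#' the denominator convention matters for convention-sensitive figures like
#' full-length paralog identities, so it is stated here and configurable
#' parameters are echoed in the result.
#'
#' @param a,b one-letter amino-acid sequences.
#' @param substitution_matrix scoring matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties.
#' @return object of class `AlignmentResult`: `identity_pct`,
#'   `n_identical`, `n_aligned` (non-gap pairs), `alignment_length`
#'   (including gaps), `pairs` (data.frame of aligned positions), and the
#'   aligned strings.
#' @export
sequence_align <- function(a, b, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) .stop_data("empty sequence")
  .check_aa(a, "sequence a"); .check_aa(b, "sequence b")
  # canonical argument order: when equally scoring alignments exist, the
  # dynamic-programming tie-break depends on which sequence is the pattern;
  # aligning in a fixed order and swapping back makes identity symmetric
  if (a > b) {
    r <- sequence_align(b, a, substitution_matrix, gap_open, gap_extend)
    pairs <- r$pairs[, c("pos_b", "pos_a", "aa_b", "aa_a")]
    names(pairs) <- c("pos_a", "pos_b", "aa_a", "aa_b")
    r$pairs <- pairs
    tmp <- r$aligned_a; r$aligned_a <- r$aligned_b; r$aligned_b <- tmp
    return(r)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  pairs <- data.frame(pos_a = ia[both], pos_b = ib[both],
                      aa_a = pa[both], aa_b = pb[both],
                      stringsAsFactors = FALSE)
  n_id <- sum(pairs$aa_a == pairs$aa_b)
  structure(list(
    identity_pct = if (nrow(pairs)) 100 * n_id / nrow(pairs) else 0,
    n_identical = n_id, n_aligned = nrow(pairs),
    alignment_length = length(pa), pairs = pairs,
    aligned_a = paste(pa, collapse = ""),
    aligned_b = paste(pb, collapse = ""),
    params = list(substitution_matrix = substitution_matrix,
                  gap_open = gap_open, gap_extend = gap_extend)
  ), class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: %.1f%% identity (%d/%d aligned pairs, alignment length %d)\n",
              x$identity_pct, x$n_identical, x$n_aligned,
              x$alignment_length))
  invisible(x)
}

#' Sequence-guided structure superposition with outlier rejection
#'
#' Matches residues of two chains by global sequence alignment, collects
#' coordinates of the chosen atom type, and fits iteratively: after each
#' Kabsch fit, pairs deviating more than `outlier_sd` standard deviations of
#' the per-pair deviation (with an absolute floor of 3.5 A) are discarded
#' and the fit repeated until a fixed point or `max_iter` rounds.  The
#' "used out of total" pair counts mirror the way outlier-rejected RMSDs
#' are customarily reported.
#'
#' @param model_a,model_b `StructureModel`s.
#' @param chain_a,chain_b chain ids (default: first polymer chain).
#' @param atoms `"CA"` for C-alpha-only fitting, or `"heavy"` to match all
#'   heavy atoms by name within aligned residues.
#' @param outlier_sd rejection threshold in SDs of the deviation
#'   distribution (default 2.0); set `Inf` to disable rejection.
#' @param max_iter maximum rejection rounds.
#' @return a `SuperpositionResult` with `n_pairs_used` (surviving pairs) and
#'   `n_pairs_total` (all matched pairs).
#' @export
structure_superpose <- function(model_a, model_b,
                                chain_a = chain_ids(model_a, TRUE)[1],
                                chain_b = chain_ids(model_b, TRUE)[1],
                                atoms = c("CA", "heavy"),
                                outlier_sd = 2.0, max_iter = 10) {
  atoms <- match.arg(atoms)
  model_a <- resolve_altlocs(model_a); model_b <- resolve_altlocs(model_b)
  ca <- get_chain(model_a, chain_a); cb <- get_chain(model_b, chain_b)
  al <- sequence_align(polymer_sequence(ca), polymer_sequence(cb))
  if (atoms == "CA") {
    xa <- .residue_atom_xyz(ca, "CA"); xb <- .residue_atom_xyz(cb, "CA")
    P <- xa[al$pairs$pos_a, , drop = FALSE]
    Q <- xb[al$pairs$pos_b, , drop = FALSE]
  } else {
    PQ <- .matched_heavy_atoms(ca, cb, al$pairs)
    P <- PQ$P; Q <- PQ$Q
  }
  ok <- stats::complete.cases(P) & stats::complete.cases(Q)
  P <- P[ok, , drop = FALSE]; Q <- Q[ok, , drop = FALSE]
  total <- nrow(P)
  if (total < 3) .stop_data("alignment too short: only %d matched atom pairs",
                            total)
  keep <- rep(TRUE, total)
  fit <- NULL
  for (iter in seq_len(max_iter)) {
    fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    dev <- sqrt(rowSums((apply_superposition(fit, P) - Q)^2))
    cutoff <- max(outlier_sd * sd(dev[keep]), 3.5)
    if (!is.finite(cutoff)) break
    new_keep <- keep & dev <= cutoff
    if (sum(new_keep) < 3 || identical(new_keep, keep)) break
    keep <- new_keep
  }
  fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
  fit$n_pairs_total <- total
  fit$n_pairs_used <- sum(keep)
  fit
}

#' @importFrom stats complete.cases
.matched_heavy_atoms <- function(chain_a, chain_b, pairs) {
  pa <- chain_a$atoms[chain_a$atoms$is_polymer &
                        chain_a$atoms$element != "H", , drop = FALSE]
  pb <- chain_b$atoms[chain_b$atoms$is_polymer &
                        chain_b$atoms$element != "H", , drop = FALSE]
  rka <- residue_table(pa)$key; rkb <- residue_table(pb)$key
  P <- NULL; Q <- NULL
  for (k in seq_len(nrow(pairs))) {
    aa <- pa[.residue_key(pa) == rka[pairs$pos_a[k]], , drop = FALSE]
    ab <- pb[.residue_key(pb) == rkb[pairs$pos_b[k]], , drop = FALSE]
    common <- intersect(aa$name, ab$name)
    if (!length(common)) next
    ia <- match(common, aa$name); ib <- match(common, ab$name)
    P <- rbind(P, cbind(aa$x[ia], aa$y[ia], aa$z[ia]))
    Q <- rbind(Q, cbind(ab$x[ib], ab$y[ib], ab$z[ib]))
  }
  list(P = P, Q = Q)
}
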