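# Hard six-criterion screen and soft ranking over candidate carrier chains.
#
# Criteria (strictness follows the published thresholds verbatim):
#   (i)   size:         length < max_length            (strict <)
#   (ii)  disulfides:   none
#   (iii) ligands:      no non-water het residues
#   (iv)  resolution:   X-ray and resolution < max_resolution (strict <;
#                       a missing resolution fails)
#   (v)   termini:      terminal CA distance <= max_termini_distance
#   (vi)  globularity:  Rg ratio <= max_globularity

#' Screening criteria thresholds
#'
#' @param max_length maximum residue count, exclusive (default 400).
#' @param max_resolution maximum resolution in Angstrom, exclusive
#'   (default 1.6).
#' @param require_xray require an X-ray diffraction method string.
#' @param forbid_disulfides disallow any disulfide bond.
#' @param forbid_ligands disallow any non-water het residue.
#' @param max_termini_distance maximum N/C terminal C-alpha separation in
#'   Angstrom, inclusive (default 10).
#' @param max_globularity maximum Rg ratio (default 1.25), inclusive.
#' @return object of class `ScreenCriteria`.
#' @export
screen_criteria <- function(max_length = 400, max_resolution = 1.6,
                            require_xray = TRUE, forbid_disulfides = TRUE,
                            forbid_ligands = TRUE,
                            max_termini_distance = 10,
                            max_globularity = 1.25) {
  num <- c(max_length = max_length, max_resolution = max_resolution,
           max_termini_distance = max_termini_distance,
           max_globularity = max_globularity)
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad)) .stop_usage("criteria thresholds must be positive: %s",
                               paste(bad, collapse = ", "))
  structure(list(max_length = max_length, max_resolution = max_resolution,
                 require_xray = isTRUE(require_xray),
                 forbid_disulfides = isTRUE(forbid_disulfides),
                 forbid_ligands = isTRUE(forbid_ligands),
                 max_termini_distance = max_termini_distance,
                 max_globularity = max_globularity),
            class = "ScreenCriteria")
}

.criterion_names <- c("size", "disulfides", "ligands", "resolution",
                      "termini", "globularity")

#' Evaluate one chain against the screening criteria
#'
#' @param descriptor a `ChainDescriptor` from [describe_chain()].
#' @param criteria a `ScreenCriteria` (defaults to [screen_criteria()]).
#' @return object of class `CandidateReport`: per-criterion verdicts with
#'   the measured values, `overall_pass` (the conjunction of all six), and
#'   the descriptor snapshot.  `soft_score` is `NA` until [rank_candidates()]
#'   normalizes over a batch.
#' @export
evaluate_candidate <- function(descriptor, criteria = screen_criteria()) {
  d <- descriptor
  res_ok <- !is.na(d$resolution) && d$resolution < criteria$max_resolution
  if (criteria$require_xray) {
    res_ok <- res_ok && !is.na(d$method) && grepl("X-RAY", toupper(d$method))
  }
  n_lig <- sum(d$ligands)
  verdicts <- data.frame(
    criterion = .criterion_names,
    value = c(d$length, d$n_disulfides, n_lig,
              if (is.na(d$resolution)) NA_real_ else d$resolution,
              d$termini_ca_distance, d$globularity),
    pass = c(d$length < criteria$max_length,
             !criteria$forbid_disulfides || d$n_disulfides == 0,
             !criteria$forbid_ligands || n_lig == 0,
             res_ok,
             d$termini_ca_distance <= criteria$max_termini_distance,
             d$globularity <= criteria$max_globularity),
    stringsAsFactors = FALSE)
  structure(list(entry_id = d$entry_id, chain_id = d$chain_id,
                 verdicts = verdicts, overall_pass = all(verdicts$pass),
                 soft_score = NA_real_, descriptor = d),
            class = "CandidateReport")
}

#' @export
print.CandidateReport <- function(x, ...) {
  cat(sprintf("CandidateReport %s chain %s: %s\n", x$entry_id, x$chain_id,
              if (x$overall_pass) "PASS" else "fail"))
  v <- x$verdicts
  for (k in seq_len(nrow(v))) {
    cat(sprintf("  %-12s %-5s (%s)\n", v$criterion[k],
                if (v$pass[k]) "pass" else "FAIL", format(v$value[k])))
  }
  invisible(x)
}

.minmax <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Rank passing candidates by a heuristic soft score
#'
#' The published screen lists B-factors, surface charge distribution and
#' compactness only as factors that "were considered"; no formula exists, so
#' the score here is an explicit, configurable heuristic.  Each badness term
#' — B-factor mean, |net surface charge| per residue, globularity — is
#' min-max normalized over the batch, and
#' `soft_score = sum(w_k * (1 - normalized badness_k))`; higher is better.
#' Ties break by entry id, then chain id, lexicographically.
#'
#' @param reports list of `CandidateReport`s.
#' @param weights numeric weights for the `bfactor`, `charge`, `globularity`
#'   terms (normalized to sum 1; default equal thirds).
#' @return the passing reports, ordered best-first, with `soft_score` and
#'   `rank` filled in.
#' @export
rank_candidates <- function(reports,
                            weights = c(bfactor = 1, charge = 1,
                                        globularity = 1) / 3) {
  w <- weights / sum(weights)
  pass <- Filter(function(r) isTRUE(r$overall_pass), reports)
  if (!length(pass)) return(list())
  b <- vapply(pass, function(r) r$descriptor$bfactor_mean, numeric(1))
  q <- vapply(pass, function(r) {
    nc <- r$descriptor$net_surface_charge
    if (is.na(nc)) 0 else abs(nc) / r$descriptor$length
  }, numeric(1))
  g <- vapply(pass, function(r) r$descriptor$globularity, numeric(1))
  score <- w[["bfactor"]] * (1 - .minmax(b)) +
    w[["charge"]] * (1 - .minmax(q)) +
    w[["globularity"]] * (1 - .minmax(g))
  ids <- vapply(pass, function(r) r$entry_id, character(1))
  chs <- vapply(pass, function(r) r$chain_id, character(1))
  ord <- order(-score, ids, chs)
  out <- pass[ord]
  for (k in seq_along(out)) {
    out[[k]]$soft_score <- score[ord][k]
    out[[k]]$rank <- k
  }
  out
}

#' Screen a library of structure files
#'
#' Reads every file, describes every polymer chain, evaluates the criteria
#' and assembles one report row per chain.  Unreadable files are skipped
#' with a warning (count in attribute `n_skipped`); if nothing is readable
#' the screen errors.
#'
#' @param paths character vector of PDB/mmCIF files.
#' @param criteria a `ScreenCriteria`.
#' @param sasa_n_points SASA quadrature points for the charge census.
#' @param compute_sasa set `FALSE` to skip the surface-charge columns (much
#'   faster; hard criteria are unaffected).
#' @return data.frame, one row per polymer chain, with descriptor columns,
#'   per-criterion `pass_*` flags, `overall_pass` and `soft_score`, sorted
#'   file order first, then ranked candidates carry ranks.
#' @export
screen_library <- function(paths, criteria = screen_criteria(),
                           sasa_n_points = 240, compute_sasa = TRUE) {
  if (!length(paths)) .stop_data("no structure files to screen")
  reports <- list()
  n_skipped <- 0L
  for (p in paths) {
    model <- tryCatch(read_structure(p), error = function(e) {
      warning(sprintf("skipping unreadable file '%s': %s", p,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(model)) { n_skipped <- n_skipped + 1L; next }
    for (ch in chain_ids(model, polymer_only = TRUE)) {
      desc <- describe_chain(model, ch, sasa_n_points = sasa_n_points,
                             compute_sasa = compute_sasa)
      rep_ <- evaluate_candidate(desc, criteria)
      rep_$file <- p
      reports[[length(reports) + 1L]] <- rep_
    }
  }
  if (!length(reports)) .stop_data("no readable structure files among %d inputs",
                                   length(paths))
  ranked <- rank_candidates(reports)
  rank_key <- vapply(ranked, function(r) paste(r$file, r$chain_id),
                     character(1))
  rows <- lapply(reports, function(r) {
    d <- r$descriptor
    v <- r$verdicts
    i <- match(paste(r$file, r$chain_id), rank_key)
    data.frame(file = r$file, entry_id = r$entry_id, chain = r$chain_id,
               length = d$length, mw = d$mw, resolution = d$resolution,
               method = d$method, n_disulfides = d$n_disulfides,
               n_ligands = sum(d$ligands),
               termini_ca_distance = d$termini_ca_distance,
               globularity = d$globularity,
               bfactor_mean = d$bfactor_mean,
               net_surface_charge = d$net_surface_charge,
               pass_size = v$pass[1], pass_disulfides = v$pass[2],
               pass_ligands = v$pass[3], pass_resolution = v$pass[4],
               pass_termini = v$pass[5], pass_globularity = v$pass[6],
               overall_pass = r$overall_pass,
               soft_score = if (is.na(i)) NA_real_ else
                 ranked[[i]]$soft_score,
               rank = if (is.na(i)) NA_integer_ else ranked[[i]]$rank,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
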