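# Per-chain structural descriptors feeding the screening criteria:
# length, mass, disulfides, ligand census, termini proximity, compactness,
# B-factor statistics and surface charge.

#' Detect disulfide bonds
#'
#' Finds CYS SG-SG pairs within `sg_sg_max`, pairing greedily nearest-first
#' so each cysteine participates in at most one bond.
#'
#' @param model a `StructureModel` with altlocs resolved.
#' @param sg_sg_max maximum SG-SG distance in Angstrom (typical bond
#'   2.05 A; default 2.5 A allows refinement slack).
#' @return data.frame with one row per bond: `chain_i`, `resno_i`,
#'   `chain_j`, `resno_j`, `distance`.
#' @export
detect_disulfides <- function(model, sg_sg_max = 2.5) {
  a <- model$atoms
  sg <- a[a$resname == "CYS" & a$name == "SG" & a$is_polymer, , drop = FALSE]
  empty <- data.frame(chain_i = character(0), resno_i = integer(0),
                      chain_j = character(0), resno_j = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(sg)
  if (n < 2) return(empty)
  xyz <- cbind(sg$x, sg$y, sg$z)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  ok <- d <= sg_sg_max
  pairs <- pairs[ok, , drop = FALSE]
  d <- d[ok]
  if (!length(d)) return(empty)
  ord <- order(d)
  used <- rep(FALSE, n)
  out <- empty
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out <- rbind(out, data.frame(
      chain_i = sg$chain[i], resno_i = sg$resno[i],
      chain_j = sg$chain[j], resno_j = sg$resno[j],
      distance = d[k], stringsAsFactors = FALSE))
  }
  out
}

#' Ligand census
#'
#' Counts non-water het residues per het code.  Waters (HOH/DOD/...) are
#' never counted; codes in `ignore` (e.g. cryo additives the user accepts)
#' are excluded.
#'
#' @param model a `StructureModel`.
#' @param ignore character vector of het codes to exclude.
#' @return named integer vector of counts per het code (empty when apo).
#' @export
ligand_census <- function(model, ignore = character(0)) {
  rt <- residue_table(model$atoms)
  het <- rt[!rt$is_polymer & !rt$is_water &
              !(rt$resname %in% ignore), , drop = FALSE]
  if (nrow(het) == 0) return(setNames(integer(0), character(0)))
  tab <- table(het$resname)
  setNames(as.integer(tab), names(tab))
}

#' Distance between terminal C-alpha atoms
#'
#' Euclidean distance between the C-alpha atoms of the first and last
#' resolved polymer residues of a chain.  If a terminal residue lacks a
#' C-alpha the computation walks inward to the nearest residue that has one
#' and flags the result via attribute `termini_resolved = FALSE`.
#'
#' @param chain a `Chain` (see [get_chain()]).
#' @return distance in Angstrom, with attributes `resno_first`,
#'   `resno_last` and `termini_resolved`.
#' @export
termini_ca_distance <- function(chain) {
  ca <- .residue_atom_xyz(chain, "CA")
  has <- which(!is.na(ca[, 1]))
  rt <- residue_table(chain$atoms[chain$atoms$is_polymer, , drop = FALSE])
  if (nrow(rt) < 2) .stop_data("chain '%s' has fewer than 2 polymer residues",
                               chain$chain_id)
  if (length(has) < 2) .stop_data("chain '%s' has fewer than 2 C-alpha atoms",
                                  chain$chain_id)
  i <- has[1]; j <- has[length(has)]
  d <- sqrt(sum((ca[i, ] - ca[j, ])^2))
  structure(d, resno_first = rt$resno[i], resno_last = rt$resno[j],
            termini_resolved = (i == 1 && j == nrow(rt)))
}

#' Radius of gyration of a chain
#'
#' Unweighted root-mean-square distance of heavy atoms from their centroid.
#'
#' @param chain a `Chain`.
#' @param heavy_only exclude hydrogens (default `TRUE`).
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(chain, heavy_only = TRUE) {
  a <- chain$atoms[chain$atoms$is_polymer, , drop = FALSE]
  if (heavy_only) a <- a[a$element != "H", , drop = FALSE]
  if (nrow(a) < 3) .stop_data("need at least 3 heavy atoms for Rg")
  xyz <- cbind(a$x, a$y, a$z)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Globularity ratio
#'
#' Ratio of the observed radius of gyration to the empirical globular
#' scaling Rg_ref = 2.2 * N^0.38 A (N = polymer residue count).  Values near
#' or below 1 indicate compact globular chains; extended chains score well
#' above 1.  Smaller is more compact.
#'
#' @param chain a `Chain`.
#' @return dimensionless ratio Rg_obs / Rg_ref.
#' @export
globularity <- function(chain) {
  rt <- residue_table(chain$atoms[chain$atoms$is_polymer, , drop = FALSE])
  n <- nrow(rt)
  radius_of_gyration(chain) / (2.2 * n^0.38)
}

#' Surface charge census of a chain
#'
#' Counts exposed basic (Arg/Lys/His) and acidic (Asp/Glu) residues; a
#' residue is exposed when its relative SASA (computed for the chain in
#' isolation) is at least `rel_sasa_min`.
#'
#' @param model a `StructureModel` with altlocs resolved.
#' @param chain_id chain identifier.
#' @param rel_sasa_min relative-SASA exposure threshold (default 0.25).
#' @param probe,n_points SASA parameters, see [sasa()].
#' @return list with `net_surface_charge` (basic - acidic), `exposed_basic`,
#'   `exposed_acidic`.
#' @export
surface_charge <- function(model, chain_id, rel_sasa_min = 0.25,
                           probe = 1.4, n_points = 960) {
  rs <- .residue_sasa(model, chain_id, probe = probe, n_points = n_points)
  exposed <- !is.na(rs$rel_sasa) & rs$rel_sasa >= rel_sasa_min
  nb <- sum(exposed & rs$resname %in% .basic_residues)
  na_ <- sum(exposed & rs$resname %in% .acidic_residues)
  list(net_surface_charge = nb - na_, exposed_basic = nb,
       exposed_acidic = na_)
}

#' Surface-entropy-reduction candidate sites
#'
#' Lists exposed high-entropy surface residues (Lys, Glu, Gln; relative SASA
#' >= 0.25) grouped into sequence-adjacent clusters (gaps of at most 2
#' positions), with the conventional substitutions suggested: Lys -> Ala or
#' Ser, Glu -> Ala, Gln -> Ala.  Clustered sites are the classic targets for
#' surface entropy reduction to create crystal-contact-friendly patches.
#'
#' @inheritParams surface_charge
#' @param rel_sasa_min exposure threshold (default 0.25).
#' @return data.frame with `resno`, `resname`, `rel_sasa`, `cluster`,
#'   `suggestions` (e.g. `"K94A/K94S"`); zero rows when nothing is exposed.
#' @export
ser_candidates <- function(model, chain_id, rel_sasa_min = 0.25,
                           probe = 1.4, n_points = 960) {
  rs <- .residue_sasa(model, chain_id, probe = probe, n_points = n_points)
  cand <- rs[!is.na(rs$rel_sasa) & rs$rel_sasa >= rel_sasa_min &
               rs$resname %in% c("LYS", "GLU", "GLN"), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(resno = integer(0), resname = character(0),
                      rel_sasa = numeric(0), cluster = integer(0),
                      suggestions = character(0), stringsAsFactors = FALSE))
  }
  cand <- cand[order(cand$resno), , drop = FALSE]
  gap <- c(Inf, diff(cand$resno))
  cand$cluster <- cumsum(gap > 3)  # gap <= 2 intervening positions
  one <- .aa3to1[cand$resname]
  cand$suggestions <- ifelse(
    one == "K", sprintf("K%dA/K%dS", cand$resno, cand$resno),
    sprintf("%s%dA", one, cand$resno))
  rownames(cand) <- NULL
  cand[, c("resno", "resname", "rel_sasa", "cluster", "suggestions")]
}

#' Molecular weight of a peptide sequence
#'
#' Average-mass molecular weight: sum of free amino-acid masses minus one
#' water (18.02 Da) per peptide bond.
#'
#' @param sequence one-letter amino-acid string.
#' @return mass in Dalton.
#' @export
peptide_mw <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  m <- .aa_mass[aa]
  m[is.na(m)] <- .aa_mass[["X"]]
  sum(m) - (length(aa) - 1) * .water_mass
}

#' Full descriptor set for one chain
#'
#' Computes every quantity the screening criteria and soft ranking consume:
#' residue count, molecular weight, resolution (from the parent model's
#' metadata), disulfide count (bonds with at least one partner in this
#' chain), ligand census of the whole model, terminal C-alpha distance,
#' radius of gyration and globularity, B-factor mean/SD over polymer heavy
#' atoms, and the exposed-charge census.
#'
#' @param model a `StructureModel` (altlocs are resolved internally).
#' @param chain_id chain identifier.
#' @param sasa_n_points point count for the SASA quadrature.
#' @param compute_sasa set `FALSE` to skip the (relatively costly) surface
#'   charge census; charge fields are then `NA`.
#' @return an object of class `ChainDescriptor` (a list).
#' @export
describe_chain <- function(model, chain_id, sasa_n_points = 960,
                           compute_sasa = TRUE) {
  if (!chain_id %in% chain_ids(model)) .stop_data("unknown chain '%s'",
                                                  chain_id)
  model <- resolve_altlocs(model)
  chain <- get_chain(model, chain_id)
  seq1 <- polymer_sequence(chain)
  ss <- detect_disulfides(model)
  ss_n <- sum(ss$chain_i == chain_id | ss$chain_j == chain_id)
  td <- termini_ca_distance(chain)
  charge <- if (compute_sasa) {
    surface_charge(model, chain_id, n_points = sasa_n_points)
  } else {
    list(net_surface_charge = NA_integer_, exposed_basic = NA_integer_,
         exposed_acidic = NA_integer_)
  }
  poly <- chain$atoms[chain$atoms$is_polymer & chain$atoms$element != "H", ,
                      drop = FALSE]
  structure(list(
    entry_id = model$metadata$entry_id,
    chain_id = chain_id,
    length = nchar(seq1),
    mw = peptide_mw(seq1),
    method = model$metadata$method,
    resolution = model$metadata$resolution,
    n_disulfides = ss_n,
    ligands = ligand_census(model),
    termini_ca_distance = as.numeric(td),
    termini_resolved = attr(td, "termini_resolved"),
    rg = radius_of_gyration(chain),
    globularity = globularity(chain),
    bfactor_mean = mean(poly$b),
    bfactor_sd = if (nrow(poly) > 1) sd(poly$b) else 0,
    net_surface_charge = charge$net_surface_charge,
    exposed_basic = charge$exposed_basic,
    exposed_acidic = charge$exposed_acidic
  ), class = "ChainDescriptor")
}

#' @export
print.ChainDescriptor <- function(x, ...) {
  cat(sprintf("ChainDescriptor %s chain %s\n", x$entry_id, x$chain_id))
  cat(sprintf("  %d residues, %.1f Da, %s at %s A\n", x$length, x$mw,
              x$method, format(x$resolution)))
  cat(sprintf("  disulfides %d, ligands %d, termini CA dist %.2f A%s\n",
              x$n_disulfides, sum(x$ligands), x$termini_ca_distance,
              if (isTRUE(x$termini_resolved)) "" else " (termini unresolved)"))
  cat(sprintf("  Rg %.2f A, globularity %.2f, B %.1f +/- %.1f A^2, net surface charge %s\n",
              x$rg, x$globularity, x$bfactor_mean, x$bfactor_sd,
              format(x$net_surface_charge)))
  invisible(x)
}
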