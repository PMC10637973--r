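# Protein-protein interface census: buried surface area, hydrogen bonds and
# salt bridges across a two-set chain partition.

.check_partition <- function(model, chains_a, chains_b) {
  if (!length(chains_a) || !length(chains_b)) {
    .stop_usage("both partitions must contain at least one chain")
  }
  if (length(intersect(chains_a, chains_b))) {
    .stop_data("partitions overlap: %s",
               paste(intersect(chains_a, chains_b), collapse = ","))
  }
  missing <- setdiff(c(chains_a, chains_b), chain_ids(model))
  if (length(missing)) .stop_data("chains not in model: %s",
                                  paste(missing, collapse = ","))
}

#' Buried surface area of a chain partition
#'
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)`.
#' The default convention is the *total* buried area summed over both
#' partners (two-sided); the per-side value (half of it) is reported
#' alongside because both conventions circulate.
#'
#' @param model a `StructureModel` (altlocs resolved internally).
#' @param chains_a,chains_b chain ids of the two partitions.
#' @param probe,n_points SASA parameters, see [sasa()].
#' @return list with `bsa` (total, two-sided, A^2), `bsa_per_side`,
#'   `sasa_a`, `sasa_b`, `sasa_complex` and the `convention` label.
#' @export
buried_surface_area <- function(model, chains_a, chains_b, probe = 1.4,
                                n_points = 960) {
  .check_partition(model, chains_a, chains_b)
  model <- resolve_altlocs(model)
  sa <- sum(sasa(model, probe, n_points, chains = chains_a))
  sb <- sum(sasa(model, probe, n_points, chains = chains_b))
  sab <- sum(sasa(model, probe, n_points, chains = c(chains_a, chains_b)))
  bsa <- sa + sb - sab
  list(bsa = bsa, bsa_per_side = bsa / 2, sasa_a = sa, sasa_b = sb,
       sasa_complex = sab, convention = "total buried over both partners")
}

# polar-atom table for one partition: donors and acceptors with coordinates
.polar_atoms <- function(model, chains) {
  a <- model$atoms[model$atoms$chain %in% chains & !model$atoms$is_water &
                     model$atoms$is_polymer, , drop = FALSE]
  don <- a$name == "N"
  acc <- a$name %in% c("O", "OXT")
  for (res in names(.hb_donors)) {
    don <- don | (a$resname == res & a$name %in% .hb_donors[[res]])
  }
  for (res in names(.hb_acceptors)) {
    acc <- acc | (a$resname == res & a$name %in% .hb_acceptors[[res]])
  }
  a$donor <- don
  a$acceptor <- acc
  a[don | acc, , drop = FALSE]
}

#' Hydrogen bonds across a chain partition
#'
#' Geometric criterion: a donor atom in one partition and an acceptor atom
#' in the other within `d_max`.  When explicit hydrogens are present on the
#' donor, the donor-hydrogen-acceptor angle must also exceed `dha_min`;
#' crystal structures usually lack hydrogens, in which case the
#' distance-only fallback applies.  Donor/acceptor typing comes from
#' per-residue templates (backbone N donates, backbone O accepts;
#' side-chain N/O/S atoms per residue type).
#'
#' @param model a `StructureModel`.
#' @param chains_a,chains_b the two chain sets.
#' @param d_max donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param dha_min minimum donor-H-acceptor angle in degrees (default 120),
#'   applied only when hydrogens exist.
#' @return data.frame of cross-partition contacts: donor and acceptor
#'   chain/residue/atom plus `distance`; deduplicated.
#' @export
find_hbonds <- function(model, chains_a, chains_b, d_max = 3.5,
                        dha_min = 120) {
  .check_partition(model, chains_a, chains_b)
  model <- resolve_altlocs(model)
  pa <- .polar_atoms(model, chains_a)
  pb <- .polar_atoms(model, chains_b)
  out <- rbind(.hb_pairs(model, pa, pb, d_max, dha_min),
               .hb_pairs(model, pb, pa, d_max, dha_min))
  if (nrow(out)) {
    key <- apply(out[, c("donor_chain", "donor_resno", "donor_atom",
                         "acceptor_chain", "acceptor_resno",
                         "acceptor_atom")], 1, paste, collapse = "|")
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$donor_chain, out$donor_resno, out$donor_atom), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

.hb_pairs <- function(model, donors, acceptors, d_max, dha_min) {
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resname = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resname = character(0),
                      acceptor_atom = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  d_ <- donors[donors$donor, , drop = FALSE]
  a_ <- acceptors[acceptors$acceptor, , drop = FALSE]
  if (!nrow(d_) || !nrow(a_)) return(empty)
  hyd <- model$atoms[model$atoms$element == "H", , drop = FALSE]
  has_h <- nrow(hyd) > 0
  rows <- empty
  for (i in seq_len(nrow(d_))) {
    dist <- sqrt((a_$x - d_$x[i])^2 + (a_$y - d_$y[i])^2 +
                   (a_$z - d_$z[i])^2)
    hits <- which(dist <= d_max)
    for (j in hits) {
      if (has_h) {
        hk <- hyd[hyd$chain == d_$chain[i] & hyd$resno == d_$resno[i], ,
                  drop = FALSE]
        if (nrow(hk)) {
          dh <- sqrt((hk$x - d_$x[i])^2 + (hk$y - d_$y[i])^2 +
                       (hk$z - d_$z[i])^2)
          hk <- hk[dh < 1.3, , drop = FALSE]
          if (nrow(hk)) {
            ang <- vapply(seq_len(nrow(hk)), function(k) {
              v1 <- c(d_$x[i] - hk$x[k], d_$y[i] - hk$y[k],
                      d_$z[i] - hk$z[k])
              v2 <- c(a_$x[j] - hk$x[k], a_$y[j] - hk$y[k],
                      a_$z[j] - hk$z[k])
              acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            }, numeric(1))
            if (all(ang < dha_min)) next
          }
        }
      }
      rows <- rbind(rows, data.frame(
        donor_chain = d_$chain[i], donor_resno = d_$resno[i],
        donor_resname = d_$resname[i], donor_atom = d_$name[i],
        acceptor_chain = a_$chain[j], acceptor_resno = a_$resno[j],
        acceptor_resname = a_$resname[j], acceptor_atom = a_$name[j],
        distance = dist[j], stringsAsFactors = FALSE))
    }
  }
  rows
}

#' Salt bridges across a chain partition
#'
#' Unique residue pairs with a basic side-chain nitrogen (Arg NE/NH1/NH2,
#' Lys NZ, His ND1/NE2) in one partition within `d_max` of an acidic
#' side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2) in the other.  Like-charge
#' proximities never count.
#'
#' @inheritParams find_hbonds
#' @param d_max charged-atom distance cutoff in Angstrom (default 4.0).
#' @return data.frame: basic and acidic chain/residue/names plus
#'   `min_distance`, one row per residue pair.
#' @export
find_salt_bridges <- function(model, chains_a, chains_b, d_max = 4.0) {
  .check_partition(model, chains_a, chains_b)
  model <- resolve_altlocs(model)
  charged <- function(chains, table) {
    a <- model$atoms[model$atoms$chain %in% chains & model$atoms$is_polymer, ,
                     drop = FALSE]
    keep <- rep(FALSE, nrow(a))
    for (res in names(table)) {
      keep <- keep | (a$resname == res & a$name %in% table[[res]])
    }
    a[keep, , drop = FALSE]
  }
  one_way <- function(chs_basic, chs_acidic) {
    b <- charged(chs_basic, .basic_atoms)
    ac <- charged(chs_acidic, .acidic_atoms)
    empty <- data.frame(basic_chain = character(0), basic_resno = integer(0),
                        basic_resname = character(0),
                        acidic_chain = character(0),
                        acidic_resno = integer(0),
                        acidic_resname = character(0),
                        min_distance = numeric(0), stringsAsFactors = FALSE)
    if (!nrow(b) || !nrow(ac)) return(empty)
    rows <- empty
    for (i in seq_len(nrow(b))) {
      dist <- sqrt((ac$x - b$x[i])^2 + (ac$y - b$y[i])^2 +
                     (ac$z - b$z[i])^2)
      hits <- which(dist <= d_max)
      if (length(hits)) {
        rows <- rbind(rows, data.frame(
          basic_chain = b$chain[i], basic_resno = b$resno[i],
          basic_resname = b$resname[i],
          acidic_chain = ac$chain[hits], acidic_resno = ac$resno[hits],
          acidic_resname = ac$resname[hits],
          min_distance = dist[hits], stringsAsFactors = FALSE))
      }
    }
    rows
  }
  out <- rbind(one_way(chains_a, chains_b), one_way(chains_b, chains_a))
  if (!nrow(out)) return(out)
  key <- paste(out$basic_chain, out$basic_resno, out$acidic_chain,
               out$acidic_resno, sep = "|")
  agg <- tapply(out$min_distance, key, min)
  first <- out[!duplicated(key), , drop = FALSE]
  first$min_distance <- as.numeric(agg[paste(first$basic_chain,
                                             first$basic_resno,
                                             first$acidic_chain,
                                             first$acidic_resno,
                                             sep = "|")])
  first <- first[order(first$basic_chain, first$basic_resno), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Full interface report
#'
#' Convenience wrapper combining [buried_surface_area()], [find_hbonds()]
#' and [find_salt_bridges()] into one census, the way protein-protein
#' interfaces are customarily summarized (buried area, H-bond count, salt
#' bridge count).
#'
#' @inheritParams find_hbonds
#' @param probe,n_points SASA parameters.
#' @param hbond_d_max,salt_d_max distance cutoffs.
#' @return object of class `InterfaceReport`.
#' @export
interface_report <- function(model, chains_a, chains_b, probe = 1.4,
                             n_points = 960, hbond_d_max = 3.5,
                             salt_d_max = 4.0) {
  bsa <- buried_surface_area(model, chains_a, chains_b, probe, n_points)
  hb <- find_hbonds(model, chains_a, chains_b, d_max = hbond_d_max)
  sb <- find_salt_bridges(model, chains_a, chains_b, d_max = salt_d_max)
  structure(list(partner_a = chains_a, partner_b = chains_b,
                 bsa = bsa$bsa, bsa_per_side = bsa$bsa_per_side,
                 convention = bsa$convention,
                 hbonds = hb, n_hbonds = nrow(hb),
                 salt_bridges = sb, n_salt_bridges = nrow(sb)),
            class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf("InterfaceReport %s | %s\n",
              paste(x$partner_a, collapse = "+"),
              paste(x$partner_b, collapse = "+")))
  cat(sprintf("  BSA %.0f A^2 (%s; %.0f A^2 per side)\n", x$bsa,
              x$convention, x$bsa_per_side))
  cat(sprintf("  %d hydrogen bonds, %d salt bridges\n", x$n_hbonds,
              x$n_salt_bridges))
  invisible(x)
}
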