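# Shared fixture builders and independent brute-force oracles.

residue_table <- insertag:::residue_table

# Build a StructureModel from a compact residue description:
# df columns: chain, resno, resname, name, element, x, y, z (optional b, type)
points_model <- function(df, resolution = 1.0,
                         method = "X-RAY DIFFRACTION", entry_id = "TEST") {
  n <- nrow(df)
  atoms <- data.frame(
    type = if (is.null(df$type)) "ATOM" else df$type,
    eleno = seq_len(n), name = df$name, altloc = "",
    resname = df$resname, chain = df$chain, resno = df$resno, icode = "",
    x = df$x, y = df$y, z = df$z, occ = 1,
    b = if (is.null(df$b)) 20 else df$b,
    element = df$element, stringsAsFactors = FALSE)
  structure_model(atoms, entry_id = entry_id, method = method,
                  resolution = resolution)
}

# n CYS residues (CA + SG) at uniform random coordinates in a cube; SG
# offsets a bond length or so from CA so some SG pairs land inside the
# disulfide cutoff by chance
random_cys_model <- function(seed, n_cys = 20, box = 12) {
  set.seed(seed)
  ca <- matrix(runif(3 * n_cys, 0, box), ncol = 3)
  sg <- ca + matrix(runif(3 * n_cys, -1.8, 1.8), ncol = 3)
  df <- data.frame(
    chain = "A", resno = rep(seq_len(n_cys), each = 2), resname = "CYS",
    name = rep(c("CA", "SG"), n_cys),
    element = rep(c("C", "S"), n_cys),
    x = as.vector(rbind(ca[, 1], sg[, 1])),
    y = as.vector(rbind(ca[, 2], sg[, 2])),
    z = as.vector(rbind(ca[, 3], sg[, 3])),
    stringsAsFactors = FALSE)
  points_model(df)
}

# brute-force disulfide oracle: all SG-SG pairs within cutoff, greedy
# nearest-first, each Cys used once
oracle_disulfides <- function(model, cutoff = 2.5) {
  a <- model$atoms
  sg <- a[a$resname == "CYS" & a$name == "SG", , drop = FALSE]
  n <- nrow(sg)
  cand <- NULL
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, length.out = n - i)) {
      d <- sqrt((sg$x[i] - sg$x[j])^2 + (sg$y[i] - sg$y[j])^2 +
                  (sg$z[i] - sg$z[j])^2)
      if (d <= cutoff) cand <- rbind(cand, c(i, j, d))
    }
  }
  if (is.null(cand)) return(data.frame(resno_i = integer(0),
                                       resno_j = integer(0)))
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used <- rep(FALSE, n)
  out <- NULL
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out <- rbind(out, data.frame(resno_i = sg$resno[i],
                                 resno_j = sg$resno[j]))
  }
  out[order(out$resno_i), , drop = FALSE]
}

# two-chain model with random polar and charged side-chain atoms
random_polar_model <- function(seed, n_per_chain = 8, spread = 9) {
  set.seed(seed)
  residues <- c("LYS", "ARG", "ASP", "GLU", "SER", "ASN", "ALA")
  side <- list(LYS = c("NZ", "N"), ARG = c("NH1", "N"), ASP = c("OD1", "O"),
               GLU = c("OE1", "O"), SER = c("OG", "O"), ASN = c("OD1", "N"),
               ALA = c("CB", "C"))
  rows <- NULL
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else runif(1, 2, 5)
    for (r in seq_len(n_per_chain)) {
      resname <- sample(residues, 1)
      base <- runif(3, 0, spread) + c(off, 0, 0)
      rows <- rbind(rows,
        data.frame(chain = ch, resno = r, resname = resname, name = "CA",
                   element = "C", x = base[1], y = base[2], z = base[3],
                   stringsAsFactors = FALSE),
        data.frame(chain = ch, resno = r, resname = resname,
                   name = side[[resname]][1],
                   element = side[[resname]][2],
                   x = base[1] + runif(1, -2, 2),
                   y = base[2] + runif(1, -2, 2),
                   z = base[3] + runif(1, -2, 2), stringsAsFactors = FALSE))
    }
  }
  points_model(rows)
}

# brute-force H-bond oracle: double loop over all cross-partition atom
# pairs, donor/acceptor typing from the package's templates
oracle_hbonds <- function(model, chains_a, chains_b, d_max = 3.5) {
  a <- model$atoms[model$atoms$is_polymer, , drop = FALSE]
  classify <- function(at) {
    don <- at$name == "N"
    acc <- at$name %in% c("O", "OXT")
    dtab <- insertag:::.hb_donors; atab <- insertag:::.hb_acceptors
    for (res in names(dtab)) don <- don | (at$resname == res & at$name %in% dtab[[res]])
    for (res in names(atab)) acc <- acc | (at$resname == res & at$name %in% atab[[res]])
    cbind(don, acc)
  }
  cls <- classify(a)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      ina <- a$chain[i] %in% chains_a && a$chain[j] %in% chains_b
      inb <- a$chain[i] %in% chains_b && a$chain[j] %in% chains_a
      if (!(ina || inb)) next
      if (!(cls[i, 1] && cls[j, 2])) next   # i donor, j acceptor
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= d_max) {
        out <- rbind(out, data.frame(
          donor_chain = a$chain[i], donor_resno = a$resno[i],
          donor_atom = a$name[i], acceptor_chain = a$chain[j],
          acceptor_resno = a$resno[j], acceptor_atom = a$name[j],
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# brute-force salt-bridge oracle: basic vs acidic charged atoms across the
# partition, unique residue pairs
oracle_salt_bridges <- function(model, chains_a, chains_b, d_max = 4.0) {
  a <- model$atoms[model$atoms$is_polymer, , drop = FALSE]
  btab <- insertag:::.basic_atoms; atab <- insertag:::.acidic_atoms
  isb <- rep(FALSE, nrow(a)); isa_ <- rep(FALSE, nrow(a))
  for (res in names(btab)) isb <- isb | (a$resname == res & a$name %in% btab[[res]])
  for (res in names(atab)) isa_ <- isa_ | (a$resname == res & a$name %in% atab[[res]])
  keys <- character(0)
  for (i in which(isb)) {
    for (j in which(isa_)) {
      cross <- (a$chain[i] %in% chains_a && a$chain[j] %in% chains_b) ||
        (a$chain[i] %in% chains_b && a$chain[j] %in% chains_a)
      if (!cross) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= d_max) {
        keys <- c(keys, paste(a$chain[i], a$resno[i], a$chain[j],
                              a$resno[j], sep = "|"))
      }
    }
  }
  sort(unique(keys))
}

salt_bridge_keys <- function(sb) {
  if (!nrow(sb)) return(character(0))
  sort(paste(sb$basic_chain, sb$basic_resno, sb$acidic_chain,
             sb$acidic_resno, sep = "|"))
}

hbond_keys <- function(hb) {
  if (!nrow(hb)) return(character(0))
  sort(paste(hb$donor_chain, hb$donor_resno, hb$donor_atom,
             hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_atom,
             sep = "|"))
}

random_rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
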