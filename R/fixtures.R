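# Deterministic synthetic-structure generator.  Fixtures are C-alpha traces
# (plus the functional side-chain atoms a test plants: SG, charged-group
# atoms, het ligands) with planted, manifest-recorded ground truth, so every
# descriptor, screen, design and comparison operation is testable without
# downloading archive entries.  All randomness flows from explicit seed
# arguments; the caller's RNG state is left untouched.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

.random_sequence <- function(n) {
  paste(sample(unname(.aa3to1[1:20]), n, replace = TRUE), collapse = "")
}

.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Build a CA-only StructureModel from an n x 3 trace.
.trace_to_model <- function(coords, sequence = NULL, chain_id = "A",
                            entry_id = "SYNT", resolution = 1.0,
                            method = "X-RAY DIFFRACTION", bfactor = 20) {
  n <- nrow(coords)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  aa3 <- .aa1to3[strsplit(sequence, "")[[1]]]
  aa3[is.na(aa3)] <- "ALA"
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(n), name = "CA", altloc = "",
    resname = unname(aa3), chain = chain_id, resno = seq_len(n),
    icode = "", x = coords[, 1], y = coords[, 2], z = coords[, 3], occ = 1,
    b = rep(bfactor, length.out = n), element = "C",
    stringsAsFactors = FALSE)
  structure_model(atoms, entry_id = entry_id, method = method,
                  resolution = resolution)
}

#' Ideal alpha-helical C-alpha trace
#'
#' Canonical alpha-helix geometry: 1.5 A rise and 100 degrees twist per
#' residue, C-alpha ring radius 2.3 A, straight axis.  Serves as the
#' extended (non-globular) control.
#'
#' @param n number of residues (>= 2).
#' @param sequence optional one-letter sequence (default poly-Ala); if
#'   `seed` is given and `sequence` is `"random"`, a random sequence drawn
#'   under that seed.
#' @param seed integer seed (used only for a random sequence).
#' @param chain_id,entry_id,resolution model annotation.
#' @return a `StructureModel` with one CA-only chain.
#' @export
make_ideal_helix <- function(n, sequence = NULL, seed = 1, chain_id = "A",
                             entry_id = "HELX", resolution = 1.0) {
  if (n < 2) .stop_usage("need n >= 2 residues, got %d", n)
  if (identical(sequence, "random")) {
    sequence <- .with_seed(seed, .random_sequence(n))
  }
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  coords <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  .trace_to_model(coords, sequence, chain_id, entry_id, resolution)
}

# points spaced `step` apart along a finely sampled parametric curve
.resample_curve <- function(f, t_max, n, step = 3.8) {
  tt <- seq(0, t_max, length.out = 20000)
  pts <- f(tt)
  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen))
  want <- (seq_len(n) - 1) * step
  if (max(want) > max(s)) .stop_data("curve too short for %d residues", n)
  idx <- vapply(want, function(w) which.min(abs(s - w)), integer(1))
  pts[idx, , drop = FALSE]
}

# place a final point exactly `d_first` from p_first and `bond` from p_prev
.close_terminus <- function(p_first, p_prev, d_first, bond = 3.8) {
  u <- p_prev - p_first
  D <- sqrt(sum(u^2))
  if (D < 1e-9 || D > d_first + bond || D < abs(d_first - bond)) {
    .stop_data("infeasible terminal placement: anchor separation %.1f A, target %.1f A",
               D, d_first)
  }
  u <- u / D
  a <- (d_first^2 - bond^2 + D^2) / (2 * D)
  h <- sqrt(max(0, d_first^2 - a^2))
  # deterministic perpendicular
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  p_first + a * u + h * v
}

#' Compact folded C-alpha bundle with exact termini separation
#'
#' Winds a C-alpha trace around a torus (a solenoid bent into a closed
#' ring) scaled so the chain is globular — radius of gyration well below
#' the `2.2 * n^0.38` reference — and, because the ring closes, the chain
#' ends adjacent to its start.  The final C-alpha is then placed *exactly*
#' `target_termini_d` from the first (and 3.8 A from its predecessor).
#' This emulates the geometry that makes a domain usable as a
#' loop-insertion tag: compact fold, termini a few Angstrom apart.
#'
#' @param n residues (>= 8).
#' @param target_termini_d exact terminal C-alpha separation in Angstrom
#'   (>= 3.8).
#' @param seed integer seed (random sequence when `sequence = "random"`).
#' @param sequence optional one-letter sequence (default poly-Ala).
#' @param chain_id,entry_id,resolution model annotation.
#' @return a `StructureModel`.
#' @export
make_compact_bundle <- function(n, target_termini_d = 6.3, seed = 1,
                                sequence = NULL, chain_id = "A",
                                entry_id = "BNDL", resolution = 1.0) {
  if (n < 8) .stop_usage("need n >= 8 residues, got %d", n)
  if (target_termini_d < 3.8) .stop_usage("target termini distance below one CA-CA bond (3.8 A)")
  if (identical(sequence, "random")) {
    sequence <- .with_seed(seed, .random_sequence(n))
  }
  rg_ref <- 2.2 * n^0.38
  rc <- 0.7 * rg_ref
  rm_ <- 0.45 * rg_ref
  # toroidal solenoid with an integer winding number closes on itself; the
  # chain stops an arc gap `delta` short of closure so the final residue can
  # be placed exactly target_termini_d from the first.
  pts <- NULL
  for (delta in target_termini_d + c(1, 2, 3.5, 5, 0.2)) {
    len_total <- (n - 2) * 3.8 + delta
    leff <- len_total / (2 * pi)
    om <- max(2, round(sqrt(max(leff^2 - rc^2, (1.2 * rm_)^2)) / rm_))
    tt <- seq(0, 2 * pi, length.out = 20000)
    curve <- cbind((rc + rm_ * cos(om * tt)) * cos(tt),
                   (rc + rm_ * cos(om * tt)) * sin(tt),
                   rm_ * sin(om * tt))
    s0 <- sum(sqrt(rowSums(diff(curve)^2)))
    curve <- curve * (len_total / s0)
    s <- c(0, cumsum(sqrt(rowSums(diff(curve)^2))))
    want <- (seq_len(n - 1) - 1) * 3.8
    idx <- vapply(want, function(w) which.min(abs(s - w)), integer(1))
    cand <- curve[idx, , drop = FALSE]
    D <- sqrt(sum((cand[n - 1, ] - cand[1, ])^2))
    if (abs(D - target_termini_d) <= 3.75 && D > 1e-6) {
      pts <- cand
      break
    }
  }
  if (is.null(pts)) .stop_data("cannot realize termini distance %.1f A with %d residues",
                               target_termini_d, n)
  last <- .close_terminus(pts[1, ], pts[n - 1, ], target_termini_d)
  .trace_to_model(rbind(pts, last), sequence, chain_id, entry_id,
                  resolution)
}

#' Extended hairpin trace with close termini
#'
#' Two long antiparallel strands joined by a turn: the termini end up a few
#' Angstrom apart (placed exactly `target_termini_d`), but the chain is far
#' from globular.  Used to plant a chain that fails the globularity
#' criterion while passing the termini-proximity one.
#'
#' @inheritParams make_compact_bundle
#' @return a `StructureModel`.
#' @export
make_hairpin <- function(n, target_termini_d = 6.3, seed = 1,
                         sequence = NULL, chain_id = "A",
                         entry_id = "HPIN", resolution = 1.0) {
  if (n < 8) .stop_usage("need n >= 8 residues, got %d", n)
  if (identical(sequence, "random")) {
    sequence <- .with_seed(seed, .random_sequence(n))
  }
  m1 <- ceiling((n - 1) / 2)
  out <- cbind(3.8 * (seq_len(m1) - 1), 0, 0)
  m2 <- n - 1 - m1
  back <- cbind(3.8 * (m1 - seq_len(m2)), 5.5, 0)
  pts <- rbind(out, back)
  last <- .close_terminus(pts[1, ], pts[n - 1, ], target_termini_d)
  .trace_to_model(rbind(pts, last), sequence, chain_id, entry_id,
                  resolution)
}

#' Plant a disulfide bond in a fixture
#'
#' Renames residues `res_i`/`res_j` to CYS and adds SG atoms positioned on
#' the line between their C-alphas, exactly `sg_distance` apart.
#'
#' @param model a `StructureModel`.
#' @param res_i,res_j author residue numbers (first chain by default).
#' @param sg_distance planted SG-SG distance in Angstrom (default 2.04, a
#'   typical disulfide bond length).
#' @param chain_id chain holding both residues.
#' @return the modified model.
#' @export
plant_disulfide <- function(model, res_i, res_j, sg_distance = 2.04,
                            chain_id = chain_ids(model)[1]) {
  a <- model$atoms
  ca <- function(res) {
    k <- which(a$chain == chain_id & a$resno == res & a$name == "CA")
    if (!length(k)) .stop_data("residue %s/%d not found", chain_id, res)
    k[1]
  }
  i <- ca(res_i); j <- ca(res_j)
  a$resname[a$chain == chain_id & a$resno %in% c(res_i, res_j)] <- "CYS"
  pi_ <- c(a$x[i], a$y[i], a$z[i]); pj <- c(a$x[j], a$y[j], a$z[j])
  mid <- (pi_ + pj) / 2
  u <- pj - pi_
  u <- u / sqrt(sum(u^2))
  sgi <- mid - u * sg_distance / 2
  sgj <- mid + u * sg_distance / 2
  sg <- data.frame(
    type = "ATOM", eleno = max(a$eleno) + 1:2, name = "SG", altloc = "",
    resname = "CYS", chain = chain_id, resno = c(res_i, res_j), icode = "",
    x = c(sgi[1], sgj[1]), y = c(sgi[2], sgj[2]), z = c(sgi[3], sgj[3]),
    occ = 1, b = a$b[i], element = "S", is_polymer = TRUE,
    is_water = FALSE, stringsAsFactors = FALSE)
  model$atoms <- rbind(a, sg)
  model
}

#' Add a het ligand residue to a fixture
#'
#' @param model a `StructureModel`.
#' @param code three-letter het code (e.g. "SO4", "GOL").
#' @param xyz coordinates; default 8 A outside the structure centroid along
#'   x.
#' @param chain_id chain to attach the het residue to.
#' @return the modified model.
#' @export
add_het_ligand <- function(model, code = "SO4", xyz = NULL,
                           chain_id = chain_ids(model)[1]) {
  a <- model$atoms
  if (is.null(xyz)) {
    xyz <- c(max(a$x) + 8, mean(a$y), mean(a$z))
  }
  elem <- c(SO4 = "S", GOL = "C", NO3 = "N", PO4 = "P", CD = "CD",
            EDO = "C", CL = "CL", ZN = "ZN")[code]
  if (is.na(elem)) elem <- "C"
  het <- data.frame(
    type = "HETATM", eleno = max(a$eleno) + 1L,
    name = unname(elem), altloc = "", resname = code, chain = chain_id,
    resno = max(a$resno[a$chain == chain_id]) + 100L, icode = "",
    x = round(xyz[1], 3), y = round(xyz[2], 3), z = round(xyz[3], 3),
    occ = 1, b = 30, element = unname(elem), is_polymer = FALSE,
    is_water = FALSE, stringsAsFactors = FALSE)
  model$atoms <- rbind(a, het)
  model
}

#' Add a water molecule to a fixture
#'
#' @inheritParams add_het_ligand
#' @return the modified model.
#' @export
add_water <- function(model, xyz = NULL, chain_id = chain_ids(model)[1]) {
  a <- model$atoms
  if (is.null(xyz)) xyz <- c(min(a$x) - 6, mean(a$y), mean(a$z))
  w <- data.frame(
    type = "HETATM", eleno = max(a$eleno) + 1L, name = "O", altloc = "",
    resname = "HOH", chain = chain_id,
    resno = max(a$resno[a$chain == chain_id]) + 200L, icode = "",
    x = round(xyz[1], 3), y = round(xyz[2], 3), z = round(xyz[3], 3),
    occ = 1, b = 40, element = "O", is_polymer = FALSE, is_water = TRUE,
    stringsAsFactors = FALSE)
  model$atoms <- rbind(a, w)
  model
}

#' Perturb atom coordinates with Gaussian noise
#'
#' Adds i.i.d. N(0, sigma^2) noise to every coordinate of every atom.
#'
#' @param model a `StructureModel`.
#' @param sigma noise SD per coordinate in Angstrom.
#' @param seed integer seed.
#' @return the perturbed model.
#' @export
perturb_model <- function(model, sigma, seed = 1) {
  n <- nrow(model$atoms)
  noise <- .with_seed(seed, matrix(rnorm(3 * n, sd = sigma), n, 3))
  model$atoms$x <- model$atoms$x + noise[, 1]
  model$atoms$y <- model$atoms$y + noise[, 2]
  model$atoms$z <- model$atoms$z + noise[, 3]
  model
}

#' Apply a random rigid transformation
#'
#' Rotates by a uniformly random proper rotation and translates by a
#' uniform offset in [-20, 20] A per axis; the applied transform is
#' recorded in attribute `"transform"` (list with `rotation`,
#' `translation`).
#'
#' @param model a `StructureModel`.
#' @param seed integer seed.
#' @return the transformed model.
#' @export
rigid_transform <- function(model, seed = 1) {
  tr <- .with_seed(seed, list(rotation = .random_rotation(),
                              translation = runif(3, -20, 20)))
  xyz <- cbind(model$atoms$x, model$atoms$y, model$atoms$z)
  moved <- t(tr$rotation %*% t(xyz)) +
    matrix(tr$translation, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- moved[, 1]
  model$atoms$y <- moved[, 2]
  model$atoms$z <- moved[, 3]
  attr(model, "transform") <- tr
  model
}

#' Generate a screening library with planted verdicts
#'
#' Writes one PDB file per requested chain into `dir`.  Each chain either
#' passes all six screening criteria or violates exactly one of them:
#' `fail_i` (420 residues), `fail_ii` (planted disulfide), `fail_iii`
#' (SO4 het ligand), `fail_iv` (2.5 A resolution), `fail_v` (termini 14 A
#' apart), `fail_vi` (extended hairpin).  The manifest records the planted
#' ground truth and is the oracle for screening tests.
#'
#' @param spec named integer vector of chain counts, names among `pass`,
#'   `fail_i` ... `fail_vi`.
#' @param seed integer seed; identical seeds reproduce byte-identical files
#'   and manifest.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest: list with `seed` and a data.frame
#'   `fixtures` (`file`, `kind`, `n`, `termini_d`, `resolution`,
#'   `expected_pass`, failed criterion).  Also written to
#'   `dir/manifest.json`.
#' @export
make_screen_library <- function(spec = c(pass = 2, fail_ii = 1,
                                         fail_iii = 1, fail_v = 1,
                                         fail_vi = 1),
                                seed = 1, dir = tempfile("screenlib")) {
  kinds <- rep(names(spec), times = spec)
  if (!length(kinds)) .stop_usage("empty library spec")
  bad <- setdiff(unique(kinds),
                 c("pass", paste0("fail_", c("i", "ii", "iii", "iv", "v",
                                             "vi"))))
  if (length(bad)) .stop_usage("unknown library spec entries: %s",
                               paste(bad, collapse = ","))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- NULL
  for (k in seq_along(kinds)) {
    kind <- kinds[k]
    sub_seed <- (seed %% 1000000L) * 1000L + k
    n <- 80L + (sub_seed %% 41L)
    termini_d <- 5 + (sub_seed %% 7) * 0.5
    resolution <- 1.0 + (sub_seed %% 5) * 0.1
    failed <- NA_character_
    if (kind == "fail_i") {
      n <- 420L
      failed <- "size"
    } else if (kind == "fail_iv") {
      resolution <- 2.5
      failed <- "resolution"
    } else if (kind == "fail_v") {
      termini_d <- 14
      failed <- "termini"
    }
    entry <- sprintf("S%03d", k)
    m <- if (kind == "fail_vi") {
      failed <- "globularity"
      make_hairpin(n, termini_d, seed = sub_seed, sequence = "random",
                   entry_id = entry, resolution = resolution)
    } else {
      make_compact_bundle(n, termini_d, seed = sub_seed,
                          sequence = "random", entry_id = entry,
                          resolution = resolution)
    }
    if (kind == "fail_ii") {
      m <- plant_disulfide(m, 10L, 30L)
      failed <- "disulfides"
    } else if (kind == "fail_iii") {
      m <- add_het_ligand(m, "SO4")
      failed <- "ligands"
    }
    file <- file.path(dir, sprintf("fix_%02d_%s.pdb", k, kind))
    write_structure_pdb(m, file)
    rows <- rbind(rows, data.frame(
      file = basename(file), kind = kind, n = n, termini_d = termini_d,
      resolution = resolution, expected_pass = kind == "pass",
      failed_criterion = failed, stringsAsFactors = FALSE))
  }
  manifest <- list(seed = seed, dir = dir, fixtures = rows)
  jsonlite::write_json(list(seed = seed, fixtures = rows),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
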