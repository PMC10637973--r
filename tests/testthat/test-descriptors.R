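# Structural descriptors: disulfides, ligands, termini, compactness, SASA,
# surface charge and SER candidate sites.

test_that("disulfide detection respects the SG-SG cutoff", {
  m <- make_compact_bundle(20, 6.3, seed = 1)
  expect_equal(nrow(detect_disulfides(m)), 0)
  m2 <- plant_disulfide(m, 3, 11, sg_distance = 2.04)
  ss <- detect_disulfides(m2)
  expect_equal(nrow(ss), 1)
  expect_equal(sort(c(ss$resno_i, ss$resno_j)), c(3, 11))
  expect_equal(ss$distance, 2.04, tolerance = 1e-6)
  m3 <- plant_disulfide(m, 3, 11, sg_distance = 3.5)
  expect_equal(nrow(detect_disulfides(m3)), 0)
})

test_that("disulfide detection matches the brute-force greedy oracle on random cysteine clouds", {
  for (seed in 1:25) {
    m <- random_cys_model(seed)
    got <- detect_disulfides(m)
    want <- oracle_disulfides(m)
    got_keys <- sort(paste(pmin(got$resno_i, got$resno_j),
                           pmax(got$resno_i, got$resno_j)))
    want_keys <- sort(paste(pmin(want$resno_i, want$resno_j),
                            pmax(want$resno_i, want$resno_j)))
    expect_identical(got_keys, want_keys)
  }
})

test_that("ligand census counts het residues but never waters", {
  m <- make_compact_bundle(15, 6.3, seed = 2)
  expect_length(ligand_census(m), 0)
  m <- add_het_ligand(m, "SO4")
  for (k in 1:30) m <- add_water(m, xyz = c(-10 - k, 0, 0))
  expect_equal(ligand_census(m), c(SO4 = 1L))
  # 8OYP-like additive mix: glycerol, nitrate, phosphate, cadmium
  m2 <- make_compact_bundle(15, 6.3, seed = 3)
  for (code in c("GOL", "NO3", "PO4", "CD")) {
    m2 <- add_het_ligand(m2, code)
  }
  cen <- ligand_census(m2)
  expect_length(cen, 4)
  expect_setequal(names(cen), c("GOL", "NO3", "PO4", "CD"))
  expect_length(ligand_census(m2, ignore = c("GOL", "NO3")), 2)
})

test_that("termini CA distance is exact on constructed coordinates and errors on single residues", {
  df <- data.frame(chain = "A", resno = 1:3, resname = "ALA", name = "CA",
                   element = "C", x = c(0, 3.1, 6.3), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  d <- termini_ca_distance(get_chain(points_model(df), "A"))
  expect_equal(as.numeric(d), 6.3)
  expect_true(attr(d, "termini_resolved"))
  one <- points_model(df[1, ])
  expect_error(termini_ca_distance(get_chain(one, "A")), "fewer than 2")
})

test_that("missing terminal CA walks inward and clears the resolved flag", {
  df <- data.frame(chain = "A", resno = 1:4, resname = "ALA",
                   name = c("CB", "CA", "CA", "CA"), element = "C",
                   x = c(0, 1, 5, 9), y = 0, z = 0, stringsAsFactors = FALSE)
  d <- termini_ca_distance(get_chain(points_model(df), "A"))
  expect_equal(as.numeric(d), 8)
  expect_false(attr(d, "termini_resolved"))
  expect_equal(attr(d, "resno_first"), 2)
})

test_that("termini distance is invariant under rigid transformation", {
  m <- make_compact_bundle(40, 7.5, seed = 4)
  d0 <- as.numeric(termini_ca_distance(get_chain(m, "A")))
  for (seed in 1:5) {
    mt <- rigid_transform(m, seed = seed)
    expect_equal(as.numeric(termini_ca_distance(get_chain(mt, "A"))), d0,
                 tolerance = 1e-9)
  }
})

test_that("radius of gyration matches hand computations", {
  # 8-atom cube of edge 2 centered at origin -> Rg = sqrt(3)
  cube <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  df <- data.frame(chain = "A", resno = 1:8, resname = "ALA", name = "CA",
                   element = "C", cube, stringsAsFactors = FALSE)
  expect_equal(radius_of_gyration(get_chain(points_model(df), "A")),
               sqrt(3), tolerance = 1e-12)
  # all atoms coincident -> Rg 0
  df0 <- transform(df, x = 0, y = 0, z = 0)
  expect_equal(radius_of_gyration(get_chain(points_model(df0), "A")), 0)
})

test_that("extended chains score higher globularity than compact bundles across lengths", {
  for (n in c(30, 80, 150, 300)) {
    g_helix <- globularity(get_chain(make_ideal_helix(n), "A"))
    g_bundle <- globularity(get_chain(make_compact_bundle(n, 6.3,
                                                          seed = n), "A"))
    expect_gt(g_helix, g_bundle)
  }
})

test_that("SASA of an isolated atom matches the analytic sphere and burial is monotone", {
  m <- points_model(data.frame(chain = "A", resno = 1, resname = "ALA",
                               name = "CA", element = "C", x = 0, y = 0,
                               z = 0, stringsAsFactors = FALSE))
  a <- sasa(m)
  expect_equal(sum(a), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # additivity for fully separated chains
  df2 <- data.frame(chain = c("A", "B"), resno = 1, resname = "ALA",
                    name = "CA", element = "C", x = c(0, 100), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  m2 <- points_model(df2)
  expect_equal(sum(sasa(m2)),
               sum(sasa(m2, chains = "A")) + sum(sasa(m2, chains = "B")),
               tolerance = 1e-9)
  # atom caged by a shell of neighbours is (nearly) fully buried, and
  # adding atoms never increases total area of the original atom
  sp <- insertag:::.sphere_points(60) * 3.0
  cage <- data.frame(chain = "A", resno = 2:61, resname = "ALA",
                     name = "CA", element = "C", x = sp[, 1], y = sp[, 2],
                     z = sp[, 3], stringsAsFactors = FALSE)
  center <- data.frame(chain = "A", resno = 1, resname = "ALA",
                       name = "CA", element = "C", x = 0, y = 0, z = 0,
                       stringsAsFactors = FALSE)
  mc <- points_model(rbind(center, cage))
  ac <- sasa(mc)
  expect_lt(ac[1], 1)   # buried center
  expect_lte(sum(ac), sum(sasa(points_model(center))) +
               sum(sasa(points_model(cage))))
})

test_that("SASA total is stable to <1% when the point count doubles", {
  m <- make_compact_bundle(40, 6.3, seed = 6, sequence = "random")
  a1 <- sum(sasa(m, n_points = 480))
  a2 <- sum(sasa(m, n_points = 960))
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("surface charge census counts exposed basic and acidic residues", {
  # isolated CA-only residues are all fully exposed
  df <- data.frame(chain = "A", resno = 1:6,
                   resname = c("LYS", "LYS", "LYS", "ASP", "ALA", "GLY"),
                   name = "CA", element = "C",
                   x = (1:6) * 10, y = 0, z = 0, stringsAsFactors = FALSE)
  sc <- surface_charge(points_model(df), "A")
  expect_equal(sc$exposed_basic, 3)
  expect_equal(sc$exposed_acidic, 1)
  expect_equal(sc$net_surface_charge, 2)
  # impossible threshold -> nothing exposed
  sc0 <- surface_charge(points_model(df), "A", rel_sasa_min = 1.01)
  expect_equal(unlist(sc0), c(net_surface_charge = 0, exposed_basic = 0,
                              exposed_acidic = 0))
  # poly-Ala has no charged residues at all
  scA <- surface_charge(make_ideal_helix(12), "A")
  expect_equal(scA$net_surface_charge, 0)
})

test_that("SER candidates cluster exposed Lys/Glu/Gln by sequence adjacency", {
  # straight extended CA trace: every residue well exposed; poly-Ala base
  # has no SER-type residues at all
  df <- data.frame(chain = "A", resno = 1:121, resname = "ALA",
                   name = "CA", element = "C", x = (1:121) * 3.8, y = 0,
                   z = 0, stringsAsFactors = FALSE)
  base <- points_model(df)
  a <- base$atoms
  a$resname[a$resno %in% c(94, 96)] <- "LYS"
  a$resname[a$resno %in% c(10, 40)] <- "LYS"
  a$resname[a$resno == 60] <- "GLU"
  m <- structure_model(a, entry_id = "SERX", resolution = 1.0)
  cand <- ser_candidates(m, "A")
  expect_setequal(cand$resno, c(10, 40, 60, 94, 96))
  got <- cand[cand$resno %in% c(94, 96), ]
  expect_equal(got$cluster[1], got$cluster[2])
  expect_equal(got$suggestions, c("K94A/K94S", "K96A/K96S"))
  far <- cand[cand$resno %in% c(10, 40), ]
  expect_false(far$cluster[1] == far$cluster[2])
  expect_equal(cand$suggestions[cand$resno == 60], "E60A")
  expect_equal(nrow(ser_candidates(base, "A")), 0)
})

test_that("chain descriptor aggregates planted properties", {
  m <- make_compact_bundle(121, 6.3, seed = 8, sequence = "random",
                           entry_id = "RDXX")
  d <- describe_chain(m, "A", sasa_n_points = 120)
  expect_s3_class(d, "ChainDescriptor")
  expect_equal(d$length, 121)
  expect_equal(d$termini_ca_distance, 6.3, tolerance = 1e-6)
  expect_equal(d$n_disulfides, 0)
  expect_equal(sum(d$ligands), 0)
  expect_equal(d$resolution, 1.0)
  expect_lt(d$globularity, 1.25)
  expect_error(describe_chain(m, "Z"), "unknown chain")
})

test_that("peptide molecular weight uses average masses minus one water per bond", {
  expect_equal(peptide_mw(strrep("G", 10)), 10 * 75.07 - 9 * 18.02,
               tolerance = 1e-9)
  expect_equal(peptide_mw("G"), 75.07)
})
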