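# Six-criterion screen: verdict logic, boundary strictness, monotonicity
# and library-level behaviour.

fake_descriptor <- function(length = 121, resolution = 1.0,
                            method = "X-RAY DIFFRACTION", n_disulfides = 0,
                            ligands = setNames(integer(0), character(0)),
                            termini = 6.3, glob = 0.9, bfactor = 20,
                            charge = 0, id = "FAKE", chain = "A") {
  structure(list(entry_id = id, chain_id = chain, length = length,
                 mw = length * 110, method = method, resolution = resolution,
                 n_disulfides = n_disulfides, ligands = ligands,
                 termini_ca_distance = termini, termini_resolved = TRUE,
                 rg = 12, globularity = glob, bfactor_mean = bfactor,
                 bfactor_sd = 5, net_surface_charge = charge,
                 exposed_basic = max(charge, 0),
                 exposed_acidic = max(-charge, 0)),
            class = "ChainDescriptor")
}

test_that("a compact high-resolution disulfide-free chain passes all six criteria", {
  rep_ <- evaluate_candidate(fake_descriptor())
  expect_true(rep_$overall_pass)
  expect_true(all(rep_$verdicts$pass))
})

test_that("boundary values follow the stated strictness of each criterion", {
  # size strictly < 400
  expect_false(evaluate_candidate(fake_descriptor(length = 400))$verdicts$pass[1])
  expect_true(evaluate_candidate(fake_descriptor(length = 399))$verdicts$pass[1])
  # resolution strictly < 1.6, missing resolution fails
  expect_false(evaluate_candidate(fake_descriptor(resolution = 1.6))$verdicts$pass[4])
  expect_false(evaluate_candidate(fake_descriptor(resolution = NA))$verdicts$pass[4])
  # termini <= 10 is inclusive
  expect_true(evaluate_candidate(fake_descriptor(termini = 10))$verdicts$pass[5])
  r <- evaluate_candidate(fake_descriptor(termini = 12))
  expect_false(r$overall_pass)
  expect_identical(r$verdicts$criterion[!r$verdicts$pass], "termini")
  # non-X-ray method fails criterion (iv)
  expect_false(evaluate_candidate(
    fake_descriptor(method = "SOLUTION NMR"))$verdicts$pass[4])
})

test_that("overall pass is the conjunction of the six verdicts on random descriptors", {
  set.seed(99)
  for (k in 1:200) {
    d <- fake_descriptor(
      length = sample(c(100, 400, 500), 1),
      resolution = sample(c(1.0, 1.7, NA), 1),
      n_disulfides = sample(0:2, 1),
      ligands = if (runif(1) < 0.5) c(SO4 = 1L) else
        setNames(integer(0), character(0)),
      termini = runif(1, 3, 15), glob = runif(1, 0.6, 2))
    r <- evaluate_candidate(d)
    expect_identical(r$overall_pass, all(r$verdicts$pass))
  }
})

test_that("relaxing a threshold never flips pass to fail and tightening never flips fail to pass", {
  set.seed(7)
  base <- screen_criteria()
  relax <- screen_criteria(max_length = 600, max_resolution = 2.5,
                           max_termini_distance = 18, max_globularity = 3)
  for (k in 1:100) {
    d <- fake_descriptor(length = sample(50:550, 1),
                         resolution = runif(1, 0.8, 2.2),
                         termini = runif(1, 3, 16),
                         glob = runif(1, 0.5, 2.5))
    p_base <- evaluate_candidate(d, base)$overall_pass
    p_relax <- evaluate_candidate(d, relax)$overall_pass
    expect_true(!p_base || p_relax)
  }
})

test_that("evaluation is a pure function of descriptor and criteria", {
  d <- fake_descriptor(termini = 9.7)
  r1 <- evaluate_candidate(d)
  r2 <- evaluate_candidate(d)
  expect_identical(r1, r2)
})

test_that("ranking is monotone in B-factor and recomputable by hand", {
  lowb <- evaluate_candidate(fake_descriptor(bfactor = 20, id = "AAA"))
  highb <- evaluate_candidate(fake_descriptor(bfactor = 40, id = "BBB"))
  ranked <- rank_candidates(list(highb, lowb))
  expect_equal(vapply(ranked, function(r) r$entry_id, ""), c("AAA", "BBB"))
  # single passing candidate ranks first whatever the weights
  solo <- rank_candidates(list(lowb), weights = c(bfactor = 5, charge = 1,
                                                  globularity = 0.1))
  expect_equal(solo[[1]]$rank, 1)
  # hand-recomputed scores for a batch of 5 planted descriptors
  descs <- list(
    fake_descriptor(bfactor = 10, charge = 0, glob = 0.8, id = "E1"),
    fake_descriptor(bfactor = 30, charge = 6, glob = 0.9, id = "E2"),
    fake_descriptor(bfactor = 20, charge = -12, glob = 1.1, id = "E3"),
    fake_descriptor(bfactor = 50, charge = 2, glob = 1.0, id = "E4"),
    fake_descriptor(bfactor = 40, charge = 1, glob = 1.2, id = "E5"))
  reports <- lapply(descs, evaluate_candidate)
  ranked5 <- rank_candidates(reports)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  b <- c(10, 30, 20, 50, 40)
  q <- abs(c(0, 6, -12, 2, 1)) / 121
  g <- c(0.8, 0.9, 1.1, 1.0, 1.2)
  score <- ((1 - mm(b)) + (1 - mm(q)) + (1 - mm(g))) / 3
  want <- c("E1", "E2", "E3", "E4", "E5")[order(-score)]
  expect_equal(vapply(ranked5, function(r) r$entry_id, ""), want)
  expect_equal(vapply(ranked5, function(r) r$soft_score, 0),
               sort(score, decreasing = TRUE), tolerance = 1e-12)
  # failing candidates are never ranked
  fail <- evaluate_candidate(fake_descriptor(termini = 12))
  expect_length(rank_candidates(list(fail)), 0)
})

test_that("library screening matches the planted manifest and is deterministic", {
  dir <- withr::local_tempdir()
  man <- make_screen_library(c(pass = 2, fail_ii = 1, fail_iii = 1,
                               fail_v = 1, fail_vi = 1), seed = 3,
                             dir = dir)
  files <- file.path(dir, man$fixtures$file)
  tab <- screen_library(files, compute_sasa = FALSE)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$overall_pass, man$fixtures$expected_pass)
  failed <- apply(tab[, paste0("pass_", c("size", "disulfides", "ligands",
                                          "resolution", "termini",
                                          "globularity"))], 1,
                  function(r) paste(c("size", "disulfides", "ligands",
                                      "resolution", "termini",
                                      "globularity")[!r], collapse = ","))
  expect_equal(failed[!man$fixtures$expected_pass],
               man$fixtures$failed_criterion[!man$fixtures$expected_pass],
               ignore_attr = TRUE)
  # determinism: screening twice yields identical tables
  expect_identical(tab, screen_library(files, compute_sasa = FALSE))
  # unreadable files are skipped with a warning, not fatal
  bad <- file.path(dir, "broken.pdb")
  writeLines("not a structure", bad)
  expect_warning(tab2 <- screen_library(c(files, bad),
                                        compute_sasa = FALSE),
                 "skipping")
  expect_equal(nrow(tab2), 6)
  expect_equal(attr(tab2, "n_skipped"), 1L)
  expect_error(suppressWarnings(screen_library(bad)), "no readable")
})
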