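test_that("single-linkage binning joins masses within the relative gap", {
  pls <- list(peak_list("a", 1, c(5000.0, 9000.0)),
              peak_list("b", 1, 5002.0))
  bins <- bin_masses(pls, 800)  # +/- 4 Da at 5 kDa; gap 2.0 joins
  expect_length(bins, 2)
  expect_equal(bins[[1]]$representative_mass, 5001.0)
  expect_equal(bins[[1]]$member_masses, c(5000.0, 5002.0))
  expect_equal(bins[[1]]$support, 2)
  expect_equal(bins[[2]]$member_masses, 9000.0)
  expect_equal(bins[[2]]$support, 1)
})

test_that("bin support counts distinct spectra, not masses", {
  pls <- list(peak_list("a", 1, 5000.0), peak_list("b", 1, 5000.0))
  bins <- bin_masses(pls, 800)
  expect_length(bins, 1)
  expect_equal(bins[[1]]$support, 2)
  # two near-identical masses in ONE spectrum still support once
  pls <- list(peak_list("a", 1, c(5000.0, 5001.0)), peak_list("b", 1, 5000.5))
  bins <- bin_masses(pls, 800)
  expect_length(bins, 1)
  expect_equal(bins[[1]]$support, 2)
  expect_length(bin_masses(list(), 800), 0)
})

test_that("binning matches exhaustive single-linkage on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:15, 1)
    masses <- round(runif(n, 4000, 12000), 2)
    tol <- sample(c(200, 800, 2000), 1)
    bins <- bin_masses(list(peak_list("s", 1, masses)), tol)
    oracle <- oracle_single_linkage(masses, tol)
    expect_length(bins, length(oracle))
    for (k in seq_along(bins)) {
      expect_equal(bins[[k]]$member_masses, oracle[[k]])
      expect_equal(bins[[k]]$representative_mass, mean(oracle[[k]]))
    }
  }
})

test_that("unanimous replicates reproduce the input mass list exactly", {
  masses <- seq(4200, 11000, by = 200)
  specimens <- lapply(1:5, function(s)
    make_specimen(sprintf("s%d", s), masses))
  ss <- build_superspectrum("A", specimens)
  expect_equal(ss$biomarker_masses, masses)
  expect_equal(ss$n_specimens, 5L)
  expect_equal(ss$n_replicates_per_specimen, 4L)
})

test_that("consensus boundary is inclusive: support 15 of 20 is kept", {
  base <- seq(4200, 11000, by = 200)  # 35 masses, all spectra
  extra <- 15000
  specimens <- lapply(1:5, function(s) {
    reps <- lapply(1:4, function(r) {
      # the extra mass appears in exactly 3 of 4 replicates -> 15/20
      m <- if (r <= 3) c(base, extra) else base
      peak_list(sprintf("s%d", s), r, m)
    })
    specimen_record(sprintf("s%d", s), "A", replicates = reps)
  })
  ss <- build_superspectrum("A", specimens, consensus_fraction = 0.75)
  expect_true(extra %in% ss$biomarker_masses)
  # 14/20 support falls below the threshold
  specimens14 <- lapply(1:5, function(s) {
    reps <- lapply(1:4, function(r) {
      m <- if ((s < 5 && r <= 3) || (s == 5 && r <= 2)) c(base, extra) else base
      peak_list(sprintf("s%d", s), r, m)
    })
    specimen_record(sprintf("s%d", s), "A", replicates = reps)
  })
  ss14 <- build_superspectrum("A", specimens14, consensus_fraction = 0.75)
  expect_false(extra %in% ss14$biomarker_masses)
})

test_that("the mass window excludes even unanimous out-of-window masses", {
  masses <- c(3500, seq(4200, 11000, by = 200))
  specimens <- lapply(1:5, function(s) make_specimen(sprintf("s%d", s), masses))
  ss <- build_superspectrum("A", specimens, mass_window = c(4000, 20000))
  expect_false(3500 %in% ss$biomarker_masses)
  expect_true(all(ss$biomarker_masses >= 4000))
})

test_that("the builder refuses low-quality replicates, naming them", {
  good <- make_specimen("s1", seq(4200, 11000, by = 200))
  bad <- specimen_record("s2", "A", replicates = list(
    peak_list("s2", 1, c(4200, 5000))))
  expect_error(build_superspectrum("A", list(good, bad)), "s2/r1")
  expect_error(build_superspectrum("A", list()), "at least one")
})

test_that("the superspectrum is invariant to specimen and replicate order", {
  set.seed(33)
  masses <- sort(runif(40, 4100, 18000))
  specimens <- lapply(1:5, function(s) {
    reps <- lapply(1:4, function(r) {
      keep <- runif(40) < 0.9
      peak_list(sprintf("s%d", s), r, masses[keep] * (1 + rnorm(sum(keep), 0, 1e-4)))
    })
    specimen_record(sprintf("s%d", s), "A", replicates = reps)
  })
  ss1 <- build_superspectrum("A", specimens)
  perm <- specimens[c(3, 1, 5, 2, 4)]
  perm <- lapply(perm, function(sp) {
    sp$replicates <- sp$replicates[c(4, 2, 1, 3)]
    sp
  })
  ss2 <- build_superspectrum("A", perm)
  expect_equal(ss1$biomarker_masses, ss2$biomarker_masses)
})

test_that("raising the consensus fraction never adds biomarkers", {
  set.seed(34)
  masses <- sort(runif(60, 4100, 18000))
  specimens <- lapply(1:5, function(s) {
    reps <- lapply(1:4, function(r) {
      keep <- runif(60) < 0.8
      peak_list(sprintf("s%d", s), r, masses[keep])
    })
    specimen_record(sprintf("s%d", s), "A", replicates = reps)
  })
  fracs <- c(0.5, 0.65, 0.75, 0.9, 1)
  sizes <- vapply(fracs, function(f) {
    length(build_superspectrum("A", specimens,
                               consensus_fraction = f)$biomarker_masses)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  for (i in seq_along(fracs)[-1]) {
    hi <- build_superspectrum("A", specimens, consensus_fraction = fracs[i])
    lo <- build_superspectrum("A", specimens, consensus_fraction = fracs[i - 1])
    expect_true(all(hi$biomarker_masses %in% lo$biomarker_masses))
  }
})

test_that("zero-noise synthetic cohorts are recovered exactly within the window", {
  cfg <- synthetic_config(n_species = 2, jitter_ppm = 0, detect_prob = 1,
                          noise_peaks_mean = 0, seed = 55)
  cohort <- simulate_cohort(cfg)
  db <- build_reference(cohort$specimens)
  for (sp in names(cohort$profiles)) {
    truth <- cohort$profiles[[sp]]$true_biomarkers
    expect_equal(db$superspectra[[sp]]$biomarker_masses,
                 truth[truth >= 4000 & truth <= 20000])
  }
})

test_that("rebuild_check compares biomarker lists 1:1 within tolerance", {
  a <- super_spectrum("A", c(5000, 8000, 12000), 800, 5, 4, c(4000, 20000))
  expect_true(rebuild_check(a, a))
  b <- super_spectrum("A", c(5000, 8000, 12000) * (1 + 1e-4), 800, 5, 4,
                      c(4000, 20000))
  expect_true(rebuild_check(a, b))  # 100 ppm apart at 800 ppm tolerance
  extra <- super_spectrum("A", c(5000, 8000, 12000, 15000), 800, 5, 4,
                          c(4000, 20000))
  expect_false(rebuild_check(a, extra))
  far <- super_spectrum("A", c(5000, 8000, 12100), 800, 5, 4, c(4000, 20000))
  expect_false(rebuild_check(a, far))
  other <- super_spectrum("B", c(5000, 8000, 12000), 800, 5, 4, c(4000, 20000))
  expect_error(rebuild_check(a, other), "species")
})
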