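ss_of <- function(species, masses, tol = 800) {
  super_spectrum(species, masses, tol, 5, 4, c(4000, 20000))
}

test_that("match_fraction counts tolerance-matched biomarkers injectively", {
  ss <- ss_of("A", c(5000, 8000, 12000, 15000))
  full <- peak_list("q", 1, c(5000, 8000, 12000, 15000))
  r <- match_fraction(full, ss)
  expect_equal(r$fraction, 1)
  expect_equal(r$matched, 4)

  three <- peak_list("q", 1, c(5000, 8000, 12000))
  r <- match_fraction(three, ss)
  expect_equal(r$fraction, 0.75)  # 3 of 4 meets the 75 % threshold

  expect_equal(match_fraction(peak_list("q", 1, numeric(0)), ss)$fraction, 0)
  expect_error(match_fraction(full, ss_of("E", numeric(0))), "no biomarkers")

  # one query mass may satisfy at most one biomarker
  close_pair <- ss_of("C", c(10000, 10009))  # 9 Da apart, both within 8 Da tol
  one_peak <- peak_list("q", 1, 10004.5)
  expect_equal(match_fraction(one_peak, close_pair)$matched, 1)
})

test_that("greedy matching equals optimal bipartite matching on small instances", {
  set.seed(202)
  for (i in 1:80) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- sort(runif(na, 4000, 4100))  # crowded region to force conflicts
    b <- sort(runif(nb, 4000, 4100))
    tol <- sample(c(500, 2000, 8000), 1)
    expect_equal(match_masses(a, b, tol)$n, oracle_max_matching(a, b, tol),
                 info = sprintf("instance %d", i))
  }
})

test_that("match_fraction is invariant under uniform mass rescaling", {
  set.seed(77)
  ss <- ss_of("A", spaced_masses(10, 4500, 18000))
  q <- peak_list("q", 1, ss$biomarker_masses * (1 + rnorm(10, 0, 3e-4)))
  base <- match_fraction(q, ss)$fraction
  for (f in c(0.5, 1.3, 2)) {
    ss2 <- super_spectrum("A", ss$biomarker_masses * f, 800, 5, 4,
                          c(4000, 20000) * f)
    q2 <- peak_list("q", 1, q$masses * f)
    expect_equal(match_fraction(q2, ss2)$fraction, base)
  }
})

test_that("replicate identification applies gate, threshold and tie order", {
  db <- list(ss_of("A", seq(5000, 12000, by = 200)),
             ss_of("B", seq(5100, 12100, by = 200)))
  self <- peak_list("q", 1, db[[1]]$biomarker_masses)
  r <- identify_replicate(self, db)
  expect_equal(r$status, "identified")
  expect_equal(r$species_call, "A")
  expect_equal(r$best_matches$fraction[1], 1)

  # high-quality spectrum of a species absent from the db
  novel <- peak_list("q", 1, seq(4001, 4001 + 56 * 30, by = 30))  # 57 masses
  expect_equal(qc_flag(novel)$data_count, 57)
  r <- identify_replicate(novel, db)
  expect_equal(r$status, "no_id_below_threshold")
  expect_true(is.na(r$species_call))
  expect_equal(nrow(r$best_matches), 2)  # audit trail retained

  # low quality wins over any match
  few <- peak_list("q", 1, db[[1]]$biomarker_masses[1:10])
  r <- identify_replicate(few, db)
  expect_equal(r$status, "no_id_low_quality")
  expect_true(is.na(r$species_call))
  expect_error(identify_replicate(self, list()), "empty")

  # exact tie on fraction and matched count resolves by species name,
  # and both reports remain visible
  db_tie <- list(ss_of("B2", seq(5000, 12000, by = 200)),
                 ss_of("A2", seq(5000, 12000, by = 200)))
  r <- identify_replicate(self, db_tie)
  expect_equal(r$species_call, "A2")
  expect_equal(r$best_matches$fraction, c(1, 1))
})

test_that("threshold comparison is inclusive at exactly 75 %", {
  db <- list(ss_of("A", c(5000, 8000, 12000, 15000)))
  q <- peak_list("q", 1, c(seq(4000, 4870, by = 30), 5000, 8000, 12000))
  r <- identify_replicate(q, db, min_count = 30)
  expect_equal(r$best_matches$fraction[1], 0.75)
  expect_equal(r$status, "identified")
})

test_that("specimen-level calls follow the replicate species set", {
  db <- list(ss_of("A", seq(5000, 12000, by = 200)),
             ss_of("B", seq(5100, 12100, by = 200)))
  hit <- function(r, sp = "A") {
    identify_replicate(peak_list("sp1", r, db[[match(sp, c("A", "B"))]]$biomarker_masses), db)
  }
  miss_low <- function(r) {
    identify_replicate(peak_list("sp1", r, c(4000, 4100)), db)
  }
  miss_sub <- function(r) {
    identify_replicate(peak_list("sp1", r, seq(13000, 13000 + 35 * 20, by = 20)), db)
  }

  res <- identify_specimen(list(hit(1), hit(2), hit(3), hit(4)))
  expect_equal(res$status, "identified")
  expect_equal(res$species_call, "A")
  expect_equal(res$level, "specimen")

  # 2 identified + 2 failures: an identification was still produced
  res <- identify_specimen(list(hit(1), hit(2), miss_low(3), miss_low(4)))
  expect_equal(res$status, "identified")
  expect_equal(res$species_call, "A")

  res <- identify_specimen(list(hit(1, "A"), hit(2, "B"), miss_low(3), miss_low(4)))
  expect_equal(res$status, "discrepant")
  expect_true(is.na(res$species_call))

  res <- identify_specimen(list(miss_low(1), miss_low(2)))
  expect_equal(res$status, "no_id_low_quality")
  res <- identify_specimen(list(miss_low(1), miss_sub(2)))
  expect_equal(res$status, "no_id_below_threshold")

  other <- identify_replicate(peak_list("sp2", 1, db[[1]]$biomarker_masses), db)
  expect_error(identify_specimen(list(hit(1), other)), "mixed specimen ids")
})

test_that("growing the database never turns an identification into no_id", {
  set.seed(303)
  base_masses <- spaced_masses(30, 4500, 18000)
  db1 <- list(ss_of("A", base_masses))
  q <- peak_list("q", 1, c(base_masses, runif(10, 4500, 18000)))
  r1 <- identify_replicate(q, db1)
  expect_equal(r1$status, "identified")
  for (i in 1:10) {
    extra <- lapply(1:i, function(k)
      ss_of(sprintf("X%02d", k), spaced_masses(30, 4500, 18000)))
    r2 <- identify_replicate(q, c(db1, extra))
    expect_equal(r2$status, "identified")
  }
})
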