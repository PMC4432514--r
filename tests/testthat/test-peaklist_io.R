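test_that("tabular peak lists parse, sort and collapse duplicates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("4123.4", "5200.1", "9871.0"), f)
  pl <- read_peaklist_table(f, "s1", 1)
  expect_s3_class(pl, "peak_list")
  expect_equal(pl$masses, c(4123.4, 5200.1, 9871.0))
  expect_equal(data_count(pl), 3)

  writeLines(c("5200.1", "4123.4"), f)
  expect_equal(read_peaklist_table(f, "s1", 1)$masses, c(4123.4, 5200.1))

  writeLines(character(0), f)
  expect_equal(data_count(read_peaklist_table(f, "s1", 1)), 0)

  # header tolerated; duplicate mass keeps the max intensity
  writeLines(c("mass,intensity", "5000,10", "5000,40", "4000,7"), f)
  pl <- read_peaklist_table(f, "s1", 1)
  expect_equal(pl$masses, c(4000, 5000))
  expect_equal(pl$intensities, c(7, 40))
})

test_that("tabular reader rejects bad rows with the offending line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("4000", "oops", "5000"), f)
  expect_error(read_peaklist_table(f, "s", 1), "line 2")
  writeLines(c("4000", "-12.5"), f)
  expect_error(read_peaklist_table(f, "s", 1), "line 2.*positive")
  expect_error(read_peaklist_table(file.path(tempdir(), "absent.txt"), "s", 1),
               "not found")
})

test_that("peak_list enforces its invariants", {
  expect_error(peak_list("s", 1, c(4000, -1)), "> 0")
  expect_error(peak_list("s", 0, 4000), ">= 1")
  expect_error(peak_list("s", 1, c(4000, 5000), intensities = 1), "length")
  pl <- peak_list("s", 1, c(5000, 4000), intensities = c(2, 9))
  expect_equal(pl$masses, c(4000, 5000))
  expect_equal(pl$intensities, c(9, 2))
})

test_that("mzXML mass lists round-trip with scan order as replicate index", {
  f <- withr::local_tempfile(fileext = ".mzXML")
  reps <- lapply(1:4, function(r) {
    peak_list("spec1", r, c(4100.25, 5200.5, 9871) + r,
              intensities = c(10, 20, 30))
  })
  write_mzxml_masslist(reps[1], f)
  out <- read_mzxml_masslist(f, specimen_id = "spec1")
  expect_length(out, 1)
  expect_equal(out[[1]]$masses, reps[[1]]$masses)
  expect_equal(out[[1]]$intensities, reps[[1]]$intensities)
  expect_equal(out[[1]]$source_format, "mzxml")

  write_mzxml_masslist(reps, f)
  out <- read_mzxml_masslist(f, specimen_id = "spec1")
  expect_length(out, 4)
  expect_equal(vapply(out, `[[`, integer(1), "replicate_index"), 1:4)
  for (r in 1:4) expect_equal(out[[r]]$masses, reps[[r]]$masses)
})

test_that("mzXML reader accepts plain-text peak pairs and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".mzXML")
  writeLines(c("<mzXML><msRun>",
               '<scan num="1"><peaks>4100.25 10 5200.5 20 9871 30</peaks></scan>',
               "</msRun></mzXML>"), f)
  out <- read_mzxml_masslist(f, specimen_id = "x")
  expect_equal(out[[1]]$masses, c(4100.25, 5200.5, 9871))

  writeLines(c("<mzXML><msRun>", '<scan num="1"><peaks>4100 10'), f)
  expect_error(read_mzxml_masslist(f), "malformed XML")

  writeLines(c("<mzXML><msRun>",
               '<scan num="1"><peaks compressionType="zlib">AAAA</peaks></scan>',
               "</msRun></mzXML>"), f)
  expect_error(read_mzxml_masslist(f), "compressionType")
})

test_that("table and mzXML readers agree on the same peaks", {
  masses <- c(4123.4, 5200.1, 9871)
  ft <- withr::local_tempfile(fileext = ".txt")
  fx <- withr::local_tempfile(fileext = ".mzXML")
  writeLines(sprintf("%.4f\t%.4f", masses, c(1, 1, 1)), ft)
  write_mzxml_masslist(list(peak_list("s1", 1, masses,
                                      intensities = c(1, 1, 1))), fx)
  a <- read_peaklist_table(ft, "s1", 1)
  b <- read_mzxml_masslist(fx, specimen_id = "s1")[[1]]
  expect_equal(a$masses, b$masses)
  expect_equal(a$intensities, b$intensities)
})

test_that("clip_to_range keeps exactly the in-window masses and is idempotent", {
  shimadzu <- instrument_profiles()$shimadzu
  pl <- peak_list("s", 1, c(2500, 10000, 22000))
  clipped <- clip_to_range(pl, shimadzu)
  expect_equal(clipped$masses, 10000)
  expect_identical(clipped$instrument$name, "shimadzu")

  inside <- peak_list("s", 1, c(4000, 15000))
  expect_equal(clip_to_range(inside, shimadzu)$masses, inside$masses)
  expect_equal(data_count(clip_to_range(peak_list("s", 1, numeric(0)),
                                        shimadzu)), 0)

  set.seed(11)
  for (i in 1:20) {
    pl <- peak_list("s", 1, sort(runif(30, 1000, 30000)))
    once <- clip_to_range(pl, shimadzu)
    twice <- clip_to_range(once, shimadzu)
    expect_equal(twice$masses, once$masses)
  }
})

test_that("instrument profiles validate their window", {
  expect_error(instrument_profile("x", 0, 100), "mass_min")
  expect_error(instrument_profile("x", 200, 100), "mass_min")
  ip <- instrument_profiles()
  expect_equal(ip$bruker$mass_min, 2000)
  expect_equal(ip$bruker$mass_max, 25000)
  expect_equal(ip$shimadzu$mass_min, 3000)
  expect_equal(ip$shimadzu$mass_max, 20000)
})

test_that("reference database JSON round-trips losslessly", {
  db <- list(
    super_spectrum("A", c(4000.1234, 5000.5678), 800, 5, 4, c(4000, 20000)),
    super_spectrum("B", c(6000.9, 9800.01), 800, 5, 4, c(4000, 20000))
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_database(db, f)
  back <- read_database(f)
  expect_equal(back, db)

  dup <- c(db, db[1])
  expect_error(write_database(dup, f), "duplicate")

  write_database(list(), f)
  expect_length(read_database(f), 0)
})

test_that("calibration offsets shift masses relatively", {
  pl <- peak_list("s", 1, c(5000, 10000))
  shifted <- apply_calibration_offset(pl, 300)
  expect_equal(shifted$masses, c(5000, 10000) * (1 + 3e-4))
  # relative matching absorbs the shift at 800 ppm tolerance
  expect_equal(match_masses(pl$masses, shifted$masses, 800)$n, 2L)
})
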