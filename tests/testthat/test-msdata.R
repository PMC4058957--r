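mgf_lines <- function(...) {
  path <- tempfile(fileext = ".mgf")
  writeLines(c(...), path)
  path
}

test_that("MGF blocks parse with sorted peaks and metadata", {
  p <- mgf_lines("BEGIN IONS", "TITLE=cmpd1", "PEPMASS=301.2 1000",
                 "COLLISION_ENERGY=20",
                 "100.1 50", "99.5 10", "250.7 40", "END IONS")
  ss <- read_mgf(p)
  expect_length(ss, 1)
  s <- ss[[1]]
  expect_identical(s$id, "cmpd1")
  expect_equal(s$precursor_mz, 301.2)
  expect_identical(s$collision_energy, "20")
  expect_equal(s$peaks$mz, c(99.5, 100.1, 250.7))  # sorted ascending
  expect_equal(s$peaks$intensity, c(10, 50, 40))
})

test_that("MGF edge cases: empty file, empty block, malformed input", {
  expect_length(read_mgf(mgf_lines("")), 0)
  expect_warning(ss <- read_mgf(mgf_lines("BEGIN IONS", "TITLE=e",
                                          "PEPMASS=100", "END IONS")),
                 "zero peaks")
  expect_length(ss, 1)
  expect_error(read_mgf(mgf_lines("BEGIN IONS", "TITLE=x", "100 1", "END IONS")),
               "PEPMASS")
  expect_error(read_mgf(mgf_lines("BEGIN IONS", "PEPMASS=100", "oops",
                                  "END IONS")), "line 3")
  expect_error(read_mgf(mgf_lines("BEGIN IONS", "PEPMASS=100", "1 2")),
               "unterminated")
})

test_that("MGF write/read round trip is bit-exact", {
  s <- ms_spectrum("rt", 200.123456789, c(50.123456789012, 180.00000001),
                   c(12.3456789, 87.6543211))
  path <- tempfile(fileext = ".mgf")
  write_mgf(list(s), path)
  s2 <- read_mgf(path)[[1]]
  expect_identical(s2$peaks$mz, s$peaks$mz)
  expect_identical(s2$peaks$intensity, s$peaks$intensity)
  expect_identical(s2$precursor_mz, s$precursor_mz)
})

test_that("amalgamation normalizes, merges within the window, and renormalizes", {
  # single spectrum: identity up to normalization
  s <- ms_spectrum("a", 300, c(100, 200), c(30, 10))
  a1 <- amalgamate(list(s))
  expect_equal(sum(a1$peaks$intensity), 100)
  expect_equal(a1$peaks$intensity, c(75, 25))
  # two energies, peaks 0.05 apart: merged at the more intense m/z
  s1 <- ms_spectrum("a", 300, 100.00, 60)
  s2 <- ms_spectrum("a", 300, 100.05, 40)
  m <- amalgamate(list(s1, s2), merge_window = 0.1)
  expect_equal(nrow(m$peaks), 1)
  expect_equal(m$peaks$mz, 100.00)  # each input normalized to 100 first
  expect_equal(m$peaks$intensity, 100)
  # peaks 0.25 apart stay separate
  s3 <- ms_spectrum("a", 300, c(100.00, 100.25), c(60, 40))
  m2 <- amalgamate(list(s3))
  expect_equal(nrow(m2$peaks), 2)
  expect_error(amalgamate(list()), "at least one")
})

test_that("amalgamation is idempotent on its own output", {
  set.seed(7)
  sp <- lapply(1:3, function(i)
    ms_spectrum("x", 400, sort(runif(15, 50, 400)), runif(15, 1, 100)))
  a <- amalgamate(sp)
  a2 <- amalgamate(list(a))
  expect_equal(a2$peaks, a$peaks)
})

test_that("peak filtering keeps the top peaks then drops weak ones", {
  # 40 peaks, all above 0.5% after normalization: exactly 30 retained
  set.seed(1)
  s <- normalize_spectrum(ms_spectrum("f", 500, seq(50, 440, 10), runif(40, 50, 100)))
  f <- filter_peaks(s)
  expect_equal(nrow(f$peaks), 30)
  expect_true(all(f$peaks$mz %in% s$peaks$mz))
  # both filters by hand: {99, .4, .3, .2, .1} -> only the 99 survives
  s2 <- ms_spectrum("g", 500, c(10, 20, 30, 40, 50), c(99, 0.4, 0.3, 0.2, 0.1))
  f2 <- filter_peaks(s2)
  expect_equal(nrow(f2$peaks), 1)
  expect_equal(f2$peaks$intensity, 99)  # not re-normalized
  # empty passes through
  e <- ms_spectrum("e", 100)
  expect_equal(nrow(filter_peaks(e)$peaks), 0)
})

test_that("filtering never invents peaks and respects the cap", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    s <- normalize_spectrum(ms_spectrum("p", 600, sort(runif(n, 50, 600)) + seq_len(n) * 1e-6,
                                        runif(n, 0, 100)))
    f <- filter_peaks(s, max_peaks = 12, min_rel_intensity = 1)
    expect_lte(nrow(f$peaks), min(12, n))
    expect_true(all(f$peaks$mz %in% s$peaks$mz))
    expect_true(all(diff(f$peaks$mz) > 0))
  }
})
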