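small_index <- function(n = 10, seed = 5, min_len = 40, max_len = 80) {
  build_index(generate_synthetic_fasta(n, min_len, max_len, seed = seed))
}

test_that("index content equals per-protein brute force, globally mass-sorted", {
  prot <- generate_synthetic_fasta(2, 40, 40, seed = 13)
  idx <- build_index(prot)
  exp_n <- sum(vapply(prot$sequence, function(s) {
    nrow(oracle_nonspecific(s, 3, 60, 300, 8000))
  }, numeric(1)))
  expect_equal(length(idx), as.integer(exp_n))
  expect_false(is.unsorted(idx$mass))
  # tie order: (mass, protein_id, start, length) ascending
  o <- order(idx$mass, idx$protein_id, idx$start, idx$length)
  expect_equal(o, seq_along(o))
  # every mass recomputes from its substring
  td <- tidy(idx)
  expect_equal(td$mass, peptide_mass(td$peptide), tolerance = 1e-12)
})

test_that("an empty database yields an empty index with all-one bucket offsets", {
  empty <- tibble::tibble(protein_id = integer(), accession = character(),
                          description = character(), sequence = character())
  idx <- build_index(empty)
  expect_equal(length(idx), 0L)
  expect_true(all(idx$bucket_offsets == 1L))
  expect_equal(query_mass_range(idx, 300, 8000)$count, 0L)
})

test_that("range queries equal the linear-scan oracle on random windows", {
  idx <- small_index(8, seed = 17)
  set.seed(31)
  for (i in 1:300) {
    b <- sort(runif(2, 250, 8100))
    got <- query_mass_range(idx, b[1], b[2])
    exp <- oracle_slice(idx, b[1], b[2])
    expect_equal(got$count, exp$count)
    if (exp$count > 0) expect_equal(got$first, exp$first)
  }
  # inclusive at both ends: query at an exact stored mass
  m <- idx$mass[100]
  got <- query_mass_range(idx, m, m)
  expect_gte(got$count, 1L)
  expect_equal(idx$mass[got$first], m)
  expect_equal(query_mass_range(idx, 1, 2)$count, 0L)
  expect_error(query_mass_range(idx, 5, 4), "lo > hi")
})

test_that("bucket lookup equals a global bisection at every integer bound", {
  idx <- small_index(4, seed = 23)
  for (b in seq(300, 8000, by = 250)) {
    expect_equal(query_mass_range(idx, b, 8000)$first,
                 findInterval(b, idx$mass, left.open = TRUE) + 1L)
  }
})

test_that("mass histogram partitions the index", {
  idx <- small_index(5, seed = 29)
  for (w in c(50, 100, 333.3)) {
    h <- index_mass_histogram(idx, w)
    expect_equal(sum(h$count), length(idx))
    # equals brute-force binning
    exp <- table(floor(idx$mass / w))
    expect_equal(h$count, as.integer(exp))
    expect_equal(h$bin_lower, as.numeric(names(exp)) * w)
  }
  one <- build_index(tibble::tibble(protein_id = 0L, accession = "a",
                                    description = "", sequence = "GGGGGG"),
                     digestion_params(min_len = 6))
  expect_equal(nrow(index_mass_histogram(one, 100)), 1L)
})

test_that("fraction_below matches direct counting at the boundaries and inside", {
  idx <- small_index(5, seed = 37)
  expect_equal(fraction_below(idx, 100), 0)
  expect_equal(fraction_below(idx, 9000), 1)
  expect_equal(fraction_below(idx, 2000), mean(idx$mass <= 2000))
})

test_that("save/load round trip is bit-exact and the record width is constant", {
  idx <- small_index(10, seed = 41)
  f <- withr::local_tempfile(fileext = ".idx")
  save_index(idx, f)
  back <- load_index(f)
  expect_identical(back$mass, idx$mass)
  expect_identical(back$protein_id, idx$protein_id)
  expect_identical(back$start, idx$start)
  expect_identical(back$length, idx$length)
  expect_identical(back$bucket_offsets, idx$bucket_offsets)
  expect_identical(back$fingerprint, idx$fingerprint)
  expect_identical(back$params$mode, idx$params$mode)
  # file size arithmetic: header + 20 bytes per record + 8 per bucket
  expect_equal(file.info(f)$size,
               148 + 20 * length(idx) + 8 * length(idx$bucket_offsets))
})

test_that("corrupt, truncated and foreign files are rejected", {
  idx <- small_index(3, seed = 43)
  f <- withr::local_tempfile(fileext = ".idx")
  save_index(idx, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw[-length(raw)], f)  # truncate by one byte
  expect_error(load_index(f), "corrupt")
  writeBin(as.raw(c(0x50, 0x4b, 0x03, 0x04, raw[-(1:4)])), f)
  expect_error(load_index(f), "magic")
})

test_that("a stale database fingerprint is surfaced at load time", {
  prot <- generate_synthetic_fasta(3, 40, 60, seed = 47)
  idx <- build_index(prot)
  f <- withr::local_tempfile(fileext = ".idx")
  save_index(idx, f)
  other <- generate_synthetic_fasta(3, 40, 60, seed = 48)
  expect_warning(back <- load_index(f, other), "stale")
  expect_null(back$proteins)
  expect_silent(back2 <- load_index(f, prot))
  expect_equal(back2$proteins$sequence, prot$sequence)
})
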