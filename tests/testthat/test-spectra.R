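test_that("MGF round trip preserves ids, precursors, charges and peaks", {
  sp <- dplyr::bind_rows(lapply(1:10, function(i) {
    synthesize_spectrum(random_peptide(8 + i %% 5), charge = 1L + i %% 3,
                        n_noise = 3, seed = i, spectrum_id = sprintf("S%02d", i))
  }))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, f)
  back <- read_mgf(f)
  expect_equal(back$spectrum_id, sp$spectrum_id)
  expect_equal(back$charge, sp$charge)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-6)
  for (i in seq_len(nrow(sp))) {
    expect_equal(back$peaks[[i]][, "mz"], sp$peaks[[i]][, "mz"], tolerance = 1e-6)
  }
})

test_that("MGF dialect rules and errors", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=t1", "PEPMASS=500.25 12345.0",
               "CHARGE=2+", "100.1 55", "END IONS"), f)
  sp <- read_mgf(f)
  expect_equal(sp$charge, 2L)                 # "2+" dialect
  expect_equal(sp$precursor_mz, 500.25)       # first PEPMASS token only
  writeLines(c("BEGIN IONS", "TITLE=t1", "CHARGE=2+", "100.1 55", "END IONS"), f)
  expect_error(read_mgf(f), "PEPMASS")
  writeLines(c("BEGIN IONS", "TITLE=t1", "PEPMASS=500.25", "100.1 55"), f)
  expect_error(read_mgf(f), "unterminated")
  writeLines(c("BEGIN IONS", "TITLE=t1", "PEPMASS=500.25", "100.1 55",
               "END IONS"), f)
  expect_warning(sp <- read_mgf(f), "assuming 2")
  expect_equal(sp$charge, 2L)
})

test_that("neutral mass inverts the charge relation", {
  sp1 <- tibble::tibble(spectrum_id = "a", precursor_mz = 500.0, charge = 1L,
                        peaks = list(matrix(numeric(), ncol = 2)))
  expect_equal(neutral_mass(sp1), 498.992724, tolerance = 1e-9)
  # [M+2H]2+ and [M+H]+ of the same peptide give the same M
  M <- peptide_mass("SAMPLEK")
  z1 <- (M + 1 * 1.007276) / 1
  z2 <- (M + 2 * 1.007276) / 2
  sp <- tibble::tibble(spectrum_id = c("a", "b"), precursor_mz = c(z1, z2),
                       charge = c(1L, 2L), peaks = list(NULL, NULL))
  expect_equal(neutral_mass(sp), c(M, M), tolerance = 1e-9)
})

test_that("b/y fragments of GG and complementarity identity", {
  fr <- theoretical_fragments("GG")
  expect_equal(length(fr), 2L)
  y1 <- 57.02146372 + 18.010565 + 1.007276
  b1 <- 57.02146372 + 1.007276
  expect_equal(fr, sort(c(b1, y1)), tolerance = 1e-6)

  set.seed(61)
  for (i in 1:50) {
    pep <- random_peptide(sample(3:25, 1))
    n <- nchar(pep)
    m <- .residue_mass_by_code[utf8ToInt(pep)]
    b <- cumsum(m)[-n] + 1.007276
    y <- rev(cumsum(rev(m))[-n]) + 18.010565 + 1.007276
    M <- peptide_mass(pep)
    expect_true(all(abs(b + y - (M + 2 * 1.007276)) < 1e-6))
  }
})

test_that("a modification shifts exactly the fragments spanning its site", {
  pep <- "GAVLK"
  base <- theoretical_fragments(pep)
  shifted <- theoretical_fragments(pep, 79.966331, 1L)
  # site 1: all b-ions shift, only y5.. (full-length) would contain it -> y1..y4 unshifted
  n <- nchar(pep)
  m <- .residue_mass_by_code[utf8ToInt(pep)]
  b0 <- cumsum(m)[-n] + 1.007276
  y0 <- cumsum(rev(m))[-n] + 18.010565 + 1.007276
  expect_equal(sort(shifted), sort(c(b0 + 79.966331, y0)), tolerance = 1e-9)
  mid <- theoretical_fragments(pep, 10.0, 3L)
  expect_equal(sort(mid), sort(c(b0 + 10 * (1:4 >= 3), y0 + 10 * (1:4 >= 3))),
               tolerance = 1e-9)
  expect_error(theoretical_fragments(pep, 10.0, 9L), "inside the peptide")
})

test_that("spectrum synthesis is reproducible and exact when noiseless", {
  pep <- "SAMPLERK"
  a <- synthesize_spectrum(pep, 2L, n_noise = 5, dropout = 0.3, seed = 99)
  b <- synthesize_spectrum(pep, 2L, n_noise = 5, dropout = 0.3, seed = 99)
  expect_identical(a, b)
  clean <- synthesize_spectrum(pep, 2L, seed = 1)
  expect_equal(clean$peaks[[1]][, "mz"], theoretical_fragments(pep),
               tolerance = 1e-12)
  expect_equal(neutral_mass(clean), peptide_mass(pep), tolerance = 1e-6)
  modded <- synthesize_spectrum(pep, 2L, mod_delta = 79.966331, mod_site = 1L,
                                seed = 1)
  expect_equal(neutral_mass(modded), peptide_mass(pep) + 79.966331,
               tolerance = 1e-6)
})

test_that("query mass distribution conserves counts", {
  sp <- dplyr::bind_rows(lapply(1:20, function(i) {
    synthesize_spectrum(random_peptide(10), charge = 2L, seed = i,
                        spectrum_id = paste0("q", i))
  }))
  edges <- seq(0, 4000, by = 250)
  h <- query_mass_distribution(sp, edges)
  expect_equal(sum(h$count), 20L)
  expect_equal(h$count, as.integer(table(cut(neutral_mass(sp), edges, right = FALSE))))
  one <- query_mass_distribution(sp[1, ], edges)
  expect_equal(sum(one$count > 0), 1L)
})
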