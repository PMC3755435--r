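wide <- function(mode = "nonspecific", ...) {
  digestion_params(mode, min_mass = 1e-6, max_mass = 1e9, ...)
}

test_that("peptide_mass matches an independent residue sum", {
  expect_equal(peptide_mass("GGG"), 3 * 57.02146 + 18.010565, tolerance = 1e-3)
  set.seed(42)
  for (i in 1:25) {
    pep <- random_peptide(sample(3:30, 1))
    expect_equal(peptide_mass(pep), oracle_mass(pep), tolerance = 1e-9)
    rev_pep <- paste(rev(strsplit(pep, "")[[1]]), collapse = "")
    expect_identical(peptide_mass(pep), peptide_mass(rev_pep))
  }
  expect_error(peptide_mass(""), "non-empty")
  expect_error(peptide_mass("GXG"), "'X'")
})

test_that("nonspecific enumeration matches the closed form and brute force", {
  p5 <- tibble::tibble(protein_id = 0L, sequence = "GAVLK")
  expect_equal(nrow(enumerate_nonspecific(p5, wide())), 6L)
  expect_equal(count_nonspecific(5, 3, 60), 6L)
  expect_equal(count_nonspecific(2, 3, 60), 0L)
  expect_equal(count_nonspecific(100, 3, 60), 4031L)
  p100 <- tibble::tibble(protein_id = 0L, sequence = random_peptide(100))
  expect_equal(nrow(enumerate_nonspecific(p100, wide())), 4031L)

  set.seed(9)
  for (i in 1:5) {
    seqs <- random_peptide(30)
    prot <- tibble::tibble(protein_id = 7L, sequence = seqs)
    got <- enumerate_nonspecific(prot, digestion_params())
    exp <- oracle_nonspecific(seqs, 3, 60, 300, 8000)
    expect_equal(got$start, exp$start)
    expect_equal(got$length, exp$length)
    expect_equal(got$mass, exp$mass, tolerance = 1e-9)
    expect_true(all(got$protein_id == 7L))
    # every yielded mass equals recomputation on the substring
    expect_equal(got$mass,
                 peptide_mass(substring(seqs, got$start + 1, got$start + got$length)),
                 tolerance = 1e-12)
  }
})

test_that("undefined residues make spanning peptides disappear", {
  prot <- tibble::tibble(protein_id = 0L, sequence = "GGGXKKK")
  got <- enumerate_nonspecific(prot, wide())
  peps <- substring("GGGXKKK", got$start + 1, got$start + got$length)
  expect_false(any(grepl("X", peps)))
  expect_equal(sort(peps), sort(c("GGG", "KKK")))
})

test_that("specific digestion applies the trypsin rule", {
  prot <- tibble::tibble(protein_id = 0L, sequence = "MKRPAKG")
  pars <- wide("specific", min_len = 1, max_missed_cleavages = 0)
  got <- enumerate_specific(prot, pars)
  peps <- substring("MKRPAKG", got$start + 1, got$start + got$length)
  # cleave after K2 (next R); suppressed after R3 (next P); cleave after K6
  expect_equal(sort(peps), sort(c("MK", "RPAK", "G")))

  pars3 <- wide("specific", min_len = 3, max_missed_cleavages = 0)
  got3 <- enumerate_specific(prot, pars3)
  expect_equal(substring("MKRPAKG", got3$start + 1, got3$start + got3$length), "RPAK")

  nok <- tibble::tibble(protein_id = 0L, sequence = "GAVLIGAVLI")
  gotn <- enumerate_specific(nok, wide("specific", min_len = 1))
  expect_equal(nrow(gotn), 1L)
  expect_equal(gotn$length, 10L)

  miss <- enumerate_specific(prot, wide("specific", min_len = 1,
                                        max_missed_cleavages = 2))
  mpep <- substring("MKRPAKG", miss$start + 1, miss$start + miss$length)
  expect_setequal(mpep, c("MK", "RPAK", "G", "MKRPAK", "RPAKG", "MKRPAKG"))
})

test_that("semispecific digestion frees exactly one terminus", {
  prot <- tibble::tibble(protein_id = 0L, sequence = "MKRPAKG")
  pars <- wide("semispecific", min_len = 2, max_missed_cleavages = 99)
  got <- enumerate_semispecific(prot, pars)
  peps <- substring("MKRPAKG", got$start + 1, got$start + got$length)
  expect_true("RPA" %in% peps)  # N-terminus at the site after K2
  expect_true("PAK" %in% peps)  # C-terminus at the site after K6
  expect_false("PA" %in% peps)  # neither terminus enzymatic
  expect_equal(anyDuplicated(peps), 0L)
})

test_that("digestion sets nest: specific within semispecific within nonspecific", {
  prot <- generate_synthetic_fasta(10, 30, 120, seed = 21)
  for (i in seq_len(nrow(prot))) {
    p <- prot[i, ]
    spec <- enumerate_specific(p, wide("specific", max_missed_cleavages = 1e6))
    semi <- enumerate_semispecific(p, wide("semispecific", max_missed_cleavages = 1e6))
    nonspec <- enumerate_nonspecific(p, wide())
    expect_true(all(entry_key(spec) %in% entry_key(semi)))
    expect_true(all(entry_key(semi) %in% entry_key(nonspec)))
  }
})
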