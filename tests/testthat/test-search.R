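# A tiny database with one planted peptide per test keeps search behaviour
# auditable by hand; batch behaviour is covered on seeded benchmarks.

planted_db <- function(pep, seed = 71, n_decoys = 10) {
  decoys <- generate_synthetic_fasta(n_decoys, 60, 120, seed = seed)
  host <- paste0("AAAGG", pep, "GGKLMAA")
  prot <- tibble::tibble(
    protein_id = c(0L, decoys$protein_id + 1L),
    accession = c("HOST", decoys$accession),
    description = "", sequence = c(host, decoys$sequence))
  build_index(prot)
}

test_that("greedy scoring matches all fragments of a clean self-match", {
  pep <- "ELVISLIVESK"
  sp <- synthesize_spectrum(pep, 2L, seed = 1)
  sc <- score_psm(sp, pep)
  expect_equal(sc$matched_peaks, length(theoretical_fragments(pep)))
  expect_equal(sc$score, sc$matched_peaks + 1)  # all intensity explained
  empty <- tibble::tibble(spectrum_id = "e", precursor_mz = 400, charge = 2L,
                          peaks = list(matrix(numeric(), ncol = 2,
                                              dimnames = list(NULL, c("mz", "intensity")))))
  expect_equal(score_psm(empty, pep), list(score = 0, matched_peaks = 0L))
})

test_that("an unrelated peptide scores strictly below the self-match", {
  set.seed(73)
  for (i in 1:20) {
    pep <- random_peptide(sample(8:15, 1))
    other <- random_peptide(sample(8:15, 1))
    sp <- synthesize_spectrum(pep, 2L, seed = i)
    expect_gt(score_psm(sp, pep)$score, score_psm(sp, other)$score)
  }
})

test_that("each observed peak is used at most once in greedy matching", {
  # two fragments close to one peak: only one may claim it
  sp <- tibble::tibble(spectrum_id = "t", precursor_mz = 400, charge = 2L,
                       peaks = list(matrix(c(200.000, 100), ncol = 2,
                                           dimnames = list(NULL, c("mz", "intensity")))))
  got <- .score_peaks(sp$peaks[[1]][, 1], sp$peaks[[1]][, 2],
                      c(199.999, 200.001), fragment_tol = 0.02)
  expect_equal(got$matched_peaks, 1L)
})

test_that("closed search recovers a planted peptide at rank 1", {
  pep <- "SAMPLEVKR"
  idx <- planted_db(pep)
  sp <- synthesize_spectrum(pep, 2L, seed = 5, spectrum_id = "planted")
  psm <- search_spectrum_closed(sp, idx)
  expect_equal(psm$peptide[1], pep)
  expect_equal(psm$protein_id[1], 0L)
  expect_equal(psm$start[1], 5L)
  expect_equal(psm$rank, seq_len(nrow(psm)))
  # spectrum mass outside the index range -> empty
  far <- tibble::tibble(spectrum_id = "far", precursor_mz = 9000, charge = 2L,
                        peaks = sp$peaks)
  expect_equal(nrow(search_spectrum_closed(far, idx)), 0L)
})

test_that("closed search equals brute-force scoring of every in-window peptide", {
  bench <- simulate_benchmark(n_proteins = 10, protein_min_length = 60,
                              protein_max_length = 100, n_spectra = 15,
                              seed = 79)
  idx <- build_index(bench$proteins)
  params <- search_params()
  all_pep <- tidy(idx)
  for (i in seq_len(nrow(bench$spectra))) {
    sp <- bench$spectra[i, ]
    M <- neutral_mass(sp)
    tol <- params$precursor_tol * M / 1e6
    cand <- all_pep[all_pep$mass >= M - tol & all_pep$mass <= M + tol, ]
    scored <- lapply(seq_len(nrow(cand)), function(j) {
      score_psm(sp, cand$peptide[j], fragment_tol = params$fragment_tol)
    })
    cand$score <- vapply(scored, `[[`, numeric(1), "score")
    cand$matched_peaks <- vapply(scored, `[[`, integer(1), "matched_peaks")
    cand$precursor_delta <- M - cand$mass
    cand <- cand[cand$matched_peaks >= params$min_matched_peaks, ]
    exp <- oracle_rank(as.data.frame(cand), params$top_k)
    got <- search_spectrum_closed(sp, idx, params)
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$peptide, exp$peptide)
    expect_equal(got$score, exp$score, tolerance = 1e-12)
    expect_equal(got$start, exp$start)
  }
})

test_that("open search recovers a planted modification and its site", {
  pep <- "GAMSAPLTKR"  # S4: phospho-compatible, discriminating fragments exist
  idx <- planted_db(pep, seed = 83)
  mindex <- build_mod_index()
  sp <- synthesize_spectrum(pep, 2L, mod_delta = 79.966331, mod_site = 4L,
                            seed = 7, spectrum_id = "mod")
  psm <- search_spectrum_open(sp, idx, mindex)
  expect_equal(psm$peptide[1], pep)
  expect_equal(psm$mod_id[1], "phospho")
  expect_equal(psm$mod_site[1], 4L)
  expect_lt(abs(psm$precursor_delta[1]), 0.01)
})

test_that("open search on unmodified spectra agrees with closed search", {
  pep <- "TINYPEPKL"
  idx <- planted_db(pep, seed = 89)
  mindex <- build_mod_index()
  sp <- synthesize_spectrum(pep, 2L, seed = 11, spectrum_id = "plain")
  closed <- search_spectrum_closed(sp, idx)
  open <- search_spectrum_open(sp, idx, mindex)
  expect_equal(open$peptide[1], closed$peptide[1])
  expect_equal(open$score[1], closed$score[1])
  expect_true(is.na(open$mod_id[1]))
})

test_that("a delta matching no modification is flagged, not dropped", {
  pep <- "GGHILKME"
  idx <- planted_db(pep, seed = 97)
  mindex <- build_mod_index()
  # plant an implausible +123.456 Da shift at the N-terminal residue
  sp <- synthesize_spectrum(pep, 2L, mod_delta = 123.456, mod_site = 1L,
                            seed = 13, spectrum_id = "odd")
  psm <- search_spectrum_open(sp, idx, mindex)
  hit <- psm[psm$peptide == pep, ]
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$flag[1], "unexplained-delta")
  expect_true(is.na(hit$mod_id[1]))
  expect_equal(hit$precursor_delta[1], 123.456, tolerance = 1e-3)
})

test_that("batch search is order-invariant and matches per-spectrum calls", {
  bench <- simulate_benchmark(n_proteins = 8, protein_min_length = 60,
                              protein_max_length = 100, n_spectra = 12,
                              seed = 101)
  idx <- build_index(bench$proteins)
  fwd <- search_batch(bench$spectra, idx)
  rev_order <- bench$spectra[rev(seq_len(nrow(bench$spectra))), ]
  bwd <- search_batch(rev_order, idx)
  expect_equal(fwd, bwd)
  single <- search_spectrum_closed(bench$spectra[3, ], idx)
  expect_equal(fwd[fwd$spectrum_id == bench$spectra$spectrum_id[3], ]$peptide,
               single$peptide)
})

test_that("PSM tables are written 1-based with documented columns", {
  pep <- "SAMPLEVKR"
  idx <- planted_db(pep, seed = 103)
  sp <- synthesize_spectrum(pep, 2L, seed = 5, spectrum_id = "planted")
  psm <- search_spectrum_closed(sp, idx)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psms(psm, f)
  back <- utils::read.delim(f)
  expect_equal(back$start[1], psm$start[1] + 1L)
  expect_true(all(c("spectrum_id", "peptide", "score", "matched_peaks",
                    "precursor_delta", "mod_id", "mod_site", "flag")
                  %in% names(back)))
})
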