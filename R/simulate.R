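# Planted-peptide benchmark generator: a synthetic database plus spectra whose
# true peptides (and, optionally, one planted modification each) are known.

#' Simulate a planted-peptide benchmark
#'
#' Generates a synthetic protein database, samples `n_spectra` peptides from
#' it (each a substring satisfying the digestion length and mass windows, so
#' every planted peptide is guaranteed to be in the nonspecific index), plants
#' a modification from `mods` at a compatible site in a chosen fraction of
#' them, and synthesizes one spectrum per peptide. Deterministic for a fixed
#' seed.
#'
#' Planted peptides are drawn with length 7--25 by default: long enough that
#' an identical substring elsewhere in a random database is vanishingly
#' unlikely, so recovery can be judged by sequence identity.
#'
#' @param n_proteins,protein_min_length,protein_max_length Database shape.
#' @param n_spectra Number of spectra (one planted peptide each).
#' @param modified_fraction Fraction of spectra carrying one planted
#'   modification.
#' @param peptide_min_length,peptide_max_length Planted peptide length range.
#' @param charges Precursor charges sampled uniformly.
#' @param dropout Fragment dropout fraction passed to [synthesize_spectrum()].
#' @param n_noise Noise peaks per spectrum.
#' @param digestion A [digestion_params()]; planted peptides respect its
#'   windows.
#' @param mods Modification tibble to plant from.
#' @param seed Integer seed.
#' @return List with `proteins` (tibble), `spectra` (tibble) and `truth`
#'   (tibble: `spectrum_id`, `protein_id`, `start` 0-based, `length`,
#'   `peptide`, `charge`, `mass`, `mod_id`, `mod_delta`, `mod_site` 1-based;
#'   `mod_id` is `NA` for unmodified spectra).
#' @export
simulate_benchmark <- function(n_proteins = 50L, protein_min_length = 80L,
                               protein_max_length = 200L, n_spectra = 200L,
                               modified_fraction = 0,
                               peptide_min_length = 7L, peptide_max_length = 25L,
                               charges = c(2L, 3L), dropout = 0, n_noise = 0L,
                               digestion = digestion_params(),
                               mods = load_modifications(), seed = 1L) {
  stopifnot(modified_fraction >= 0, modified_fraction <= 1,
            peptide_min_length >= digestion$min_len,
            peptide_max_length <= digestion$max_len,
            peptide_max_length <= protein_min_length)
  seed <- as.integer(seed) %% 2147483000L
  proteins <- generate_synthetic_fasta(n_proteins, protein_min_length,
                                       protein_max_length, seed = seed)
  prot_len <- nchar(proteins$sequence)
  n_modified <- round(modified_fraction * n_spectra)
  truth <- with_preserved_seed(seed + 1L, {
    rows <- vector("list", n_spectra)
    spec_seeds <- sample.int(2147483000L, n_spectra)
    is_mod <- seq_len(n_spectra) <= n_modified
    for (i in seq_len(n_spectra)) {
      repeat {
        pid <- sample.int(n_proteins, 1L) - 1L
        L <- prot_len[pid + 1L]
        len <- sample(peptide_min_length:min(peptide_max_length, L), 1L)
        start0 <- sample.int(L - len + 1L, 1L) - 1L
        pep <- substr(proteins$sequence[pid + 1L], start0 + 1L, start0 + len)
        mass <- peptide_mass(pep)
        if (mass < digestion$min_mass || mass > digestion$max_mass) next
        mod_id <- NA_character_; mod_delta <- NA_real_; mod_site <- NA_integer_
        if (is_mod[i]) {
          m <- sample.int(nrow(mods), 1L)
          sites <- compatible_sites(pep, mods$sites[[m]],
                                    at_protein_n = start0 == 0L,
                                    at_protein_c = start0 + len == L)
          if (!length(sites)) next
          mod_id <- mods$mod_id[m]
          mod_delta <- mods$delta_mass[m]
          mod_site <- sites[sample.int(length(sites), 1L)]
        }
        rows[[i]] <- tibble::tibble(
          spectrum_id = sprintf("SYN%05d", i), protein_id = pid,
          start = start0, length = len, peptide = pep,
          charge = sample(charges, 1L), mass = mass,
          mod_id = mod_id, mod_delta = mod_delta, mod_site = mod_site,
          spec_seed = spec_seeds[i])
        break
      }
    }
    dplyr::bind_rows(rows)
  })
  spectra <- dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    synthesize_spectrum(tr$peptide, charge = tr$charge,
                        mod_delta = if (is.na(tr$mod_id)) NULL else tr$mod_delta,
                        mod_site = if (is.na(tr$mod_id)) NULL else tr$mod_site,
                        n_noise = n_noise, dropout = dropout,
                        seed = tr$spec_seed, spectrum_id = tr$spectrum_id)
  }))
  truth$spec_seed <- NULL
  list(proteins = proteins, spectra = spectra, truth = truth)
}
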