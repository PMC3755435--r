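# Tandem-mass spectra: MGF input/output, precursor mass conversion, the b/y
# fragment model, and synthetic spectrum generation with planted peptides.
#
# A spectrum collection is a tibble with one row per spectrum:
#   spectrum_id   character
#   precursor_mz  Thomson
#   charge        positive integer
#   peaks         list column of two-column matrices (mz, intensity),
#                 rows sorted ascending by mz

new_spectra <- function(spectrum_id, precursor_mz, charge, peaks) {
  tibble::tibble(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 peaks = peaks)
}

.empty_peaks <- function() {
  matrix(numeric(), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))
}

.as_peaks <- function(mz, intensity) {
  o <- order(mz)
  matrix(c(mz[o], intensity[o]), ncol = 2L,
         dimnames = list(NULL, c("mz", "intensity")))
}

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` takes its first token as
#' the precursor m/z; `CHARGE` accepts the `2+` dialect; a block without
#' `CHARGE` defaults to charge 2 with a warning. Peak lines are
#' whitespace-separated `mz intensity` pairs (a missing intensity is read
#' as 0).
#'
#' @param path Path to an MGF file.
#' @return Spectrum tibble (see above), in file order.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins))) {
    stop("malformed MGF: unterminated BEGIN IONS block", call. = FALSE)
  }
  if (!length(begins)) {
    return(new_spectra(character(), numeric(), integer(), list()))
  }
  parse_block <- function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(block)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*$", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    if (!"PEPMASS" %in% keys) {
      stop(sprintf("malformed MGF: block %d (line %d) has no PEPMASS", i, begins[i]),
           call. = FALSE)
    }
    pepmass <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1L])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else sprintf("spectrum_%d", i)
    if ("CHARGE" %in% keys) {
      charge <- as.integer(sub("\\+$", "", trimws(vals[match("CHARGE", keys)])))
    } else {
      warning(sprintf("MGF block %d has no CHARGE; assuming 2", i), call. = FALSE)
      charge <- 2L
    }
    peak_lines <- block[!kv]
    if (length(peak_lines)) {
      parts <- strsplit(peak_lines, "\\s+")
      mz <- as.numeric(vapply(parts, `[`, character(1), 1L))
      it <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "0", character(1))
      peaks <- .as_peaks(mz, as.numeric(it))
    } else {
      peaks <- .empty_peaks()
    }
    list(spectrum_id = title, precursor_mz = pepmass, charge = charge, peaks = peaks)
  }
  blocks <- lapply(seq_along(begins), parse_block)
  new_spectra(vapply(blocks, `[[`, character(1), "spectrum_id"),
              vapply(blocks, `[[`, numeric(1), "precursor_mz"),
              vapply(blocks, `[[`, integer(1), "charge"),
              lapply(blocks, `[[`, "peaks"))
}

#' Write spectra to MGF
#'
#' @param spectra Spectrum tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  fmt <- function(i) {
    pk <- spectra$peaks[[i]]
    c("BEGIN IONS",
      paste0("TITLE=", spectra$spectrum_id[i]),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]),
      sprintf("CHARGE=%d+", spectra$charge[i]),
      if (nrow(pk)) sprintf("%.6f %.4f", pk[, 1L], pk[, 2L]),
      "END IONS", "")
  }
  writeLines(unlist(lapply(seq_len(nrow(spectra)), fmt)), path)
  invisible(path)
}

#' Neutral precursor mass
#'
#' Removes the charge protons: `M = z * mz - z * 1.007276`.
#'
#' @param spectra Spectrum tibble (vectorised over rows).
#' @return Numeric vector of neutral masses in Daltons.
#' @export
neutral_mass <- function(spectra) {
  spectra$charge * spectra$precursor_mz - spectra$charge * mass_constants[["proton"]]
}

#' Theoretical b/y fragment m/z values
#'
#' Singly charged b- and y-ion series of a peptide:
#' `b_i = prefix_i + proton`, `y_i = suffix_i + water + proton`, for
#' `i = 1 .. n-1`. An optional single modification adds its delta mass to
#' every fragment containing the modified position. The returned list is
#' sorted ascending and de-duplicated at 1e-6 Da.
#'
#' @param peptide Peptide sequence (length >= 2).
#' @param mod_delta Optional modification delta mass (Da).
#' @param mod_site 1-based position of the modified residue (required with
#'   `mod_delta`).
#' @return Ascending numeric vector of fragment m/z values.
#' @examples
#' theoretical_fragments("GG")
#' @export
theoretical_fragments <- function(peptide, mod_delta = NULL, mod_site = NULL) {
  n <- nchar(peptide)
  stopifnot(n >= 2L)
  m <- .residue_mass_by_code[utf8ToInt(peptide)]
  if (anyNA(m)) stop("peptide contains a residue with undefined mass", call. = FALSE)
  proton <- mass_constants[["proton"]]; water <- mass_constants[["water"]]
  b <- cumsum(m)[-n] + proton                    # b_i = first i residues
  y <- cumsum(rev(m))[-n] + water + proton       # y_i = last i residues
  if (!is.null(mod_delta)) {
    if (is.null(mod_site) || mod_site < 1L || mod_site > n) {
      stop("mod_site must be a position inside the peptide", call. = FALSE)
    }
    i <- seq_len(n - 1L)
    b <- b + mod_delta * (i >= mod_site)        # b_i spans positions 1..i
    y <- y + mod_delta * (i >= n - mod_site + 1L)  # y_i spans positions n-i+1..n
  }
  out <- sort(c(b, y))
  keep <- c(TRUE, diff(out) > 1e-6)
  out[keep]
}

#' Synthesize a spectrum for a known peptide
#'
#' Builds the theoretical b/y peak list of the (optionally modified) peptide,
#' drops a seeded random fraction of fragments, adds uniform noise peaks, and
#' sets the precursor at `(M + delta + z * proton) / z`. Fragment intensities
#' are 100 with a small seeded jitter; noise intensities are at most 30.
#' Bitwise reproducible for a fixed seed.
#'
#' @param peptide Peptide sequence.
#' @param charge Precursor charge.
#' @param mod_delta,mod_site Optional planted modification (delta Da, 1-based
#'   site).
#' @param n_noise Number of uniform noise peaks.
#' @param noise_range m/z range for noise peaks.
#' @param dropout Fraction of fragments dropped, in `[0, 1)`.
#' @param seed Integer seed.
#' @param spectrum_id Identifier; defaults to the peptide.
#' @return One-row spectrum tibble.
#' @export
synthesize_spectrum <- function(peptide, charge = 2L, mod_delta = NULL,
                                mod_site = NULL, n_noise = 0L,
                                noise_range = c(200, 2000), dropout = 0,
                                seed = 1L, spectrum_id = peptide) {
  stopifnot(dropout >= 0, dropout < 1)
  frags <- theoretical_fragments(peptide, mod_delta, mod_site)
  delta <- if (is.null(mod_delta)) 0 else mod_delta
  proton <- mass_constants[["proton"]]
  precursor_mz <- (peptide_mass(peptide) + delta + charge * proton) / charge
  with_preserved_seed(seed, {
    keep <- stats::runif(length(frags)) >= dropout
    mz <- frags[keep]
    intensity <- 100 + stats::runif(length(mz), -10, 10)
    if (n_noise > 0L) {
      mz <- c(mz, stats::runif(n_noise, noise_range[1L], noise_range[2L]))
      intensity <- c(intensity, stats::runif(n_noise, 1, 30))
    }
    new_spectra(spectrum_id, precursor_mz, charge, list(.as_peaks(mz, intensity)))
  })
}

#' Histogram of query (precursor) masses
#'
#' Bins the neutral precursor masses of a spectrum collection at the given
#' edges; counts sum to the number of spectra.
#'
#' @param spectra Spectrum tibble (non-empty).
#' @param bin_edges Ascending numeric vector of bin edges covering all masses;
#'   bins are `[e_k, e_{k+1})`, with the last bin closed.
#' @return Tibble with `bin_lower`, `bin_upper`, `count`.
#' @export
query_mass_distribution <- function(spectra, bin_edges) {
  stopifnot(nrow(spectra) > 0L, length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  m <- neutral_mass(spectra)
  if (any(m < bin_edges[1L] | m > bin_edges[length(bin_edges)])) {
    stop("bin_edges do not cover all precursor masses", call. = FALSE)
  }
  k <- findInterval(m, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(k, nbins = length(bin_edges) - 1L)
  tibble::tibble(bin_lower = bin_edges[-length(bin_edges)],
                 bin_upper = bin_edges[-1L],
                 count = counts)
}
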