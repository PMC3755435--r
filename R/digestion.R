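# In-silico digestion: peptide masses and the three digestion semantics
# (specific, semispecific, nonspecific), with length and mass windows.
#
# Coordinates are 0-based half-open throughout: the peptide of an entry
# (protein_id, start, length) is substring [start, start + length) of the
# protein sequence, so the 1-based R substring is
# substr(seq, start + 1, start + length).

#' Enzyme cleavage rule
#'
#' A cleavage rule is a set of residues cleaved after (C-side) or before
#' (N-side), plus a set of residues that suppress cleavage when adjacent on
#' the far side of the bond. The default is trypsin: cleave after K or R
#' unless the next residue is P.
#'
#' @param cleave_after Residues at which hydrolysis occurs.
#' @param suppress_next Residues that block cleavage when they follow the bond.
#' @param side `"C"` (cleave after the listed residues) or `"N"` (before).
#' @return An object of class `enzyme_rule`.
#' @export
enzyme_rule <- function(cleave_after = c("K", "R"), suppress_next = "P",
                        side = c("C", "N")) {
  side <- match.arg(side)
  structure(list(cleave_after = toupper(cleave_after),
                 suppress_next = toupper(suppress_next),
                 side = side),
            class = "enzyme_rule")
}

#' Digestion parameters
#'
#' Bundles the digestion mode, enzyme rule and the peptide filters. The
#' default mass window (300--8000 Da, neutral monoisotopic) and length window
#' (3--60 residues) are the standard settings for exhaustive nonspecific
#' enumeration; both windows are inclusive at both ends.
#'
#' @param mode One of `"nonspecific"`, `"specific"`, `"semispecific"`.
#' @param enzyme An [enzyme_rule()] (ignored for nonspecific digestion).
#' @param min_len,max_len Inclusive peptide length bounds (residues).
#' @param min_mass,max_mass Inclusive neutral monoisotopic mass bounds (Da).
#' @param max_missed_cleavages Maximum internal cleavage sites left uncut
#'   (specific and semispecific modes only).
#' @return An object of class `digestion_params`.
#' @export
digestion_params <- function(mode = c("nonspecific", "specific", "semispecific"),
                             enzyme = enzyme_rule(),
                             min_len = 3L, max_len = 60L,
                             min_mass = 300, max_mass = 8000,
                             max_missed_cleavages = 2L) {
  mode <- match.arg(mode)
  if (!(min_len >= 1 && min_len <= max_len)) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  if (!(min_mass > 0 && min_mass <= max_mass)) {
    stop("need 0 < min_mass <= max_mass", call. = FALSE)
  }
  if (max_missed_cleavages < 0) stop("max_missed_cleavages must be >= 0", call. = FALSE)
  structure(list(mode = mode, enzyme = enzyme,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_mass = as.numeric(min_mass), max_mass = as.numeric(max_mass),
                 max_missed_cleavages = as.integer(max_missed_cleavages)),
            class = "digestion_params")
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of the monoisotopic residue masses plus one water (18.010565 Da).
#'
#' @param sequence Character vector of peptide sequences.
#' @return Numeric vector of masses in Daltons.
#' @examples
#' peptide_mass("GGG")
#' @export
peptide_mass <- function(sequence) {
  if (any(!nzchar(sequence))) stop("peptide sequence must be non-empty", call. = FALSE)
  vapply(sequence, function(s) {
    m <- .residue_mass_by_code[utf8ToInt(s)]
    if (anyNA(m)) {
      bad <- strsplit(s, "")[[1]][is.na(m)][1L]
      stop(sprintf("residue '%s' has no defined monoisotopic mass", bad),
           call. = FALSE)
    }
    sum(m) + mass_constants[["water"]]
  }, numeric(1), USE.NAMES = FALSE)
}

# Per-sequence cumulative sums used by all enumerators: cum_mass[i+1] is the
# residue-mass sum of the first i residues (NA-free; undefined residues carry
# mass 0 but are tracked in cum_bad so windows spanning them can be skipped).
.sequence_cumulants <- function(sequence) {
  codes <- utf8ToInt(sequence)
  m <- .residue_mass_by_code[codes]
  bad <- is.na(m)
  m[bad] <- 0
  list(cum_mass = c(0, cumsum(m)), cum_bad = c(0L, cumsum(bad)), n = length(codes))
}

# Shared assembly: given candidate (start0, len) pairs for one protein, filter
# by mass window and undefined residues, and return the canonical tibble
# ordered by (start, length).
.assemble_entries <- function(protein_id, cum, starts0, lens, params) {
  keep <- lens >= params$min_len & lens <= params$max_len
  starts0 <- starts0[keep]; lens <- lens[keep]
  if (!length(starts0)) {
    return(tibble::tibble(protein_id = integer(), start = integer(),
                          length = integer(), mass = numeric()))
  }
  mass <- cum$cum_mass[starts0 + lens + 1L] - cum$cum_mass[starts0 + 1L] +
    mass_constants[["water"]]
  nbad <- cum$cum_bad[starts0 + lens + 1L] - cum$cum_bad[starts0 + 1L]
  keep <- nbad == 0L & mass >= params$min_mass & mass <= params$max_mass
  starts0 <- starts0[keep]; lens <- lens[keep]; mass <- mass[keep]
  o <- order(starts0, lens)
  tibble::tibble(protein_id = rep.int(as.integer(protein_id), length(o)),
                 start = as.integer(starts0[o]), length = as.integer(lens[o]),
                 mass = mass[o])
}

#' Enumerate peptides by nonspecific digestion
#'
#' Yields every substring of the protein whose length lies in
#' `[min_len, max_len]` and whose neutral mass lies in `[min_mass, max_mass]`
#' (both inclusive), each exactly once, skipping substrings that span a
#' residue with undefined mass (B, J, O, X, Z). Rows are ordered by ascending
#' start, then ascending length.
#'
#' @param protein A one-row protein tibble (or any list with `protein_id` and
#'   `sequence`).
#' @param params A [digestion_params()] with `mode = "nonspecific"`.
#' @return Tibble with columns `protein_id`, `start` (0-based), `length`,
#'   `mass` (Da).
#' @export
enumerate_nonspecific <- function(protein, params = digestion_params()) {
  stopifnot(params$mode == "nonspecific")
  cum <- .sequence_cumulants(protein$sequence[[1]])
  L <- cum$n
  kmax <- min(params$max_len, L)
  if (kmax < params$min_len) {
    return(.assemble_entries(protein$protein_id[[1]], cum, integer(), integer(), params))
  }
  ks <- params$min_len:kmax
  lens <- rep.int(ks, L - ks + 1L)
  starts0 <- unlist(lapply(ks, function(k) 0:(L - k)), use.names = FALSE)
  .assemble_entries(protein$protein_id[[1]], cum, starts0, lens, params)
}

# 0-based cleavage boundary positions for a sequence under an enzyme rule:
# position p means the bond between residues p-1 and p (p in 1..L-1). Protein
# termini (0 and L) are not included.
cleavage_sites <- function(sequence, enzyme) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2L) return(integer())
  if (enzyme$side == "C") {
    hit <- chars[-L] %in% enzyme$cleave_after &
      !(chars[-1L] %in% enzyme$suppress_next)
  } else {
    hit <- chars[-1L] %in% enzyme$cleave_after &
      !(chars[-L] %in% enzyme$suppress_next)
  }
  which(hit)
}

#' Enumerate peptides by specific digestion
#'
#' Both peptide termini must lie at an enzymatic boundary (a cleavage site
#' under the enzyme rule, or a protein terminus), with at most
#' `max_missed_cleavages` internal sites left uncut. Filtered by the length
#' and mass windows like [enumerate_nonspecific()].
#'
#' @inheritParams enumerate_nonspecific
#' @return Tibble as in [enumerate_nonspecific()].
#' @examples
#' p <- tibble::tibble(protein_id = 0L, sequence = "MKRPAKG")
#' pars <- digestion_params("specific", min_len = 1, min_mass = 1,
#'                          max_missed_cleavages = 0)
#' enumerate_specific(p, pars)
#' @export
enumerate_specific <- function(protein, params) {
  stopifnot(params$mode %in% c("specific", "semispecific"))
  seqstr <- protein$sequence[[1]]
  cum <- .sequence_cumulants(seqstr)
  L <- cum$n
  bounds <- c(0L, cleavage_sites(seqstr, params$enzyme), L)
  nb <- length(bounds)
  starts0 <- integer(); lens <- integer()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + params$max_missed_cleavages)
    js <- (i + 1L):jmax
    starts0 <- c(starts0, rep.int(bounds[i], length(js)))
    lens <- c(lens, bounds[js] - bounds[i])
  }
  .assemble_entries(protein$protein_id[[1]], cum, starts0, lens, params)
}

#' Enumerate peptides by semispecific digestion
#'
#' At least one peptide terminus must lie at an enzymatic boundary (cleavage
#' site or protein terminus); the other terminus is unconstrained. Each
#' qualifying substring is yielded once, even when both termini qualify.
#' Internal missed cleavages are limited by `max_missed_cleavages` as in
#' specific digestion. The result always contains the specific set and is
#' contained in the nonspecific set under identical filters.
#'
#' @inheritParams enumerate_nonspecific
#' @return Tibble as in [enumerate_nonspecific()].
#' @export
enumerate_semispecific <- function(protein, params) {
  stopifnot(params$mode == "semispecific")
  seqstr <- protein$sequence[[1]]
  cum <- .sequence_cumulants(seqstr)
  L <- cum$n
  sites <- cleavage_sites(seqstr, params$enzyme)
  bounds <- c(0L, sites, L)
  is_bound <- logical(L + 1L); is_bound[bounds + 1L] <- TRUE
  # site_flag[s + 1] marks cleavage site s; cum_sites[p + 2] counts sites <= p
  site_flag <- logical(L + 1L); site_flag[sites + 1L] <- TRUE
  cum_sites <- c(0L, cumsum(site_flag))
  kmax <- min(params$max_len, L)
  if (kmax < params$min_len) {
    return(.assemble_entries(protein$protein_id[[1]], cum, integer(), integer(), params))
  }
  ks <- params$min_len:kmax
  lens <- rep.int(ks, L - ks + 1L)
  starts0 <- unlist(lapply(ks, function(k) 0:(L - k)), use.names = FALSE)
  ends0 <- starts0 + lens
  semi <- is_bound[starts0 + 1L] | is_bound[ends0 + 1L]
  # cleavage sites strictly between the termini: s with start < s < end
  internal <- cum_sites[ends0 + 1L] - cum_sites[starts0 + 2L]
  keep <- semi & internal <= params$max_missed_cleavages
  .assemble_entries(protein$protein_id[[1]], cum, starts0[keep], lens[keep], params)
}

#' Closed-form nonspecific peptide count
#'
#' Number of substrings of a length-`L` sequence with length in
#' `[min_len, max_len]`, ignoring any mass filter:
#' \eqn{\sum_{k=min}^{\min(max, L)} (L - k + 1)}. Used as the enumeration
#' oracle.
#'
#' @param L Protein length (residues).
#' @param min_len,max_len Inclusive length bounds.
#' @return Integer count (0 when `L < min_len`).
#' @examples
#' count_nonspecific(100, 3, 60)  # 4031
#' @export
count_nonspecific <- function(L, min_len = 3L, max_len = 60L) {
  stopifnot(L >= 0)
  kmax <- min(max_len, L)
  if (kmax < min_len) return(0L)
  ks <- min_len:kmax
  as.integer(sum(L - ks + 1L))
}

#' Digest a whole database
#'
#' Applies the enumerator selected by `params$mode` to every protein and binds
#' the results (per-protein enumeration order preserved).
#'
#' @param proteins Protein tibble.
#' @param params A [digestion_params()].
#' @return Tibble with columns `protein_id`, `start`, `length`, `mass`.
#' @export
digest_proteins <- function(proteins, params = digestion_params()) {
  f <- switch(params$mode,
              nonspecific = enumerate_nonspecific,
              specific = enumerate_specific,
              semispecific = enumerate_semispecific)
  if (!nrow(proteins)) {
    return(tibble::tibble(protein_id = integer(), start = integer(),
                          length = integer(), mass = numeric()))
  }
  out <- lapply(seq_len(nrow(proteins)), function(i) f(proteins[i, ], params))
  dplyr::bind_rows(out)
}

# Extract peptide strings for entry rows (0-based starts) from the database.
peptide_sequences <- function(proteins, entries) {
  seqs <- proteins$sequence[entries$protein_id + 1L]
  substr(seqs, entries$start + 1L, entries$start + entries$length)
}
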