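# The mass-sorted fixed-width peptide index.
#
# A peptide_index holds four parallel columnar arrays (mass, protein_id,
# start, length) globally sorted by (mass, protein_id, start, length), plus an
# integer-Dalton bucket offset table: for every integer b in
# [bucket_min, bucket_max + 1], bucket_offsets[b - bucket_min + 1] is the
# first (1-based) array position whose mass is >= b. A precursor-mass range
# query therefore jumps straight to the right bucket and refines with a short
# bisection inside it, giving constant expected work per lookup; a global
# bisection fallback covers queries outside the bucket table.

#' Build a mass-sorted peptide index
#'
#' Digests every protein with the enumerator selected by `params$mode` and
#' sorts all resulting index terms by (mass, protein_id, start, length)
#' ascending. Each term is the classic three-integer record (protein ID,
#' start position, length) keyed by its peptide mass. The source database is
#' fingerprinted so a stale index can be detected at search time, and is kept
#' on the in-memory object so searches can recover peptide sequences.
#'
#' @param proteins Protein tibble (see [read_fasta()]); may be empty.
#' @param params A [digestion_params()].
#' @return An object of class `peptide_index`.
#' @export
build_index <- function(proteins, params = digestion_params()) {
  entries <- digest_proteins(proteins, params)
  o <- order(entries$mass, entries$protein_id, entries$start, entries$length,
             method = "radix")
  new_peptide_index(mass = entries$mass[o],
                    protein_id = entries$protein_id[o],
                    start = entries$start[o],
                    length = entries$length[o],
                    params = params,
                    fingerprint = db_fingerprint(proteins),
                    proteins = proteins)
}

new_peptide_index <- function(mass, protein_id, start, length, params,
                              fingerprint, proteins = NULL) {
  bucket_min <- as.integer(floor(params$min_mass))
  bucket_max <- as.integer(ceiling(params$max_mass))
  b <- bucket_min:(bucket_max + 1L)
  # first 1-based position with mass >= b  ==  (# masses < b) + 1
  offsets <- findInterval(b, mass, left.open = TRUE) + 1L
  structure(list(mass = as.numeric(mass),
                 protein_id = as.integer(protein_id),
                 start = as.integer(start),
                 length = as.integer(length),
                 bucket_min = bucket_min,
                 bucket_offsets = as.integer(offsets),
                 params = params,
                 fingerprint = fingerprint,
                 proteins = proteins),
            class = "peptide_index")
}

#' @export
length.peptide_index <- function(x) length(x$mass)

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index> %d terms, %s digestion, mass %.6g-%.6g Da, length %d-%d\n",
              length(x), x$params$mode, x$params$min_mass, x$params$max_mass,
              x$params$min_len, x$params$max_len))
  cat(sprintf("  database: %s (%s proteins)\n", substr(x$fingerprint, 1, 12),
              if (is.null(x$proteins)) "detached" else nrow(x$proteins)))
  invisible(x)
}

#' Tidy a peptide index into an entry table
#'
#' @param x A `peptide_index`.
#' @param ... Unused.
#' @return Tibble with one row per index term: `mass`, `protein_id`, `start`
#'   (0-based), `length`, and `peptide` when the source database is attached.
#' @method tidy peptide_index
#' @export
tidy.peptide_index <- function(x, ...) {
  out <- tibble::tibble(mass = x$mass, protein_id = x$protein_id,
                        start = x$start, length = x$length)
  if (!is.null(x$proteins) && nrow(out)) {
    out$peptide <- peptide_sequences(x$proteins, out)
  }
  out
}

#' One-row summary of a peptide index
#'
#' @param x A `peptide_index`.
#' @param ... Unused.
#' @return One-row tibble: term count, mass range present, digestion mode,
#'   database fingerprint.
#' @method glance peptide_index
#' @export
glance.peptide_index <- function(x, ...) {
  tibble::tibble(n_terms = length(x),
                 min_mass = if (length(x)) min(x$mass) else NA_real_,
                 max_mass = if (length(x)) max(x$mass) else NA_real_,
                 mode = x$params$mode,
                 fingerprint = x$fingerprint)
}

# First 1-based position with mass >= lo, via the bucket table plus bisection
# within the bucket; falls back to a global bisection when lo is outside the
# bucket range.
.lower_bound <- function(index, lo) {
  n <- length(index$mass)
  bmin <- index$bucket_min
  bmax <- bmin + length(index$bucket_offsets) - 2L
  b <- floor(lo)
  if (is.finite(b) && b >= bmin && b <= bmax) {
    p0 <- index$bucket_offsets[b - bmin + 1L]
    p1 <- index$bucket_offsets[b - bmin + 2L]  # first position with mass >= b+1
    # bisect within [p0, p1) for the first mass >= lo
    lo_i <- p0; hi_i <- p1
    while (lo_i < hi_i) {
      mid <- (lo_i + hi_i) %/% 2L
      if (index$mass[mid] < lo) lo_i <- mid + 1L else hi_i <- mid
    }
    lo_i
  } else {
    findInterval(lo, index$mass, left.open = TRUE) + 1L
  }
}

#' Retrieve the index slice for a precursor-mass window
#'
#' Returns the maximal contiguous run of index positions whose mass lies in
#' the inclusive window `[lo, hi]`. The first position is located through the
#' integer-Dalton bucket offset table (constant expected work), the last by
#' bisection.
#'
#' @param index A `peptide_index`.
#' @param lo,hi Window bounds in Daltons, `lo <= hi`.
#' @return List with `first` (1-based position of the first in-window term;
#'   meaningless when `count` is 0) and `count`.
#' @export
query_mass_range <- function(index, lo, hi) {
  if (lo > hi) stop("query_mass_range: lo > hi", call. = FALSE)
  n <- length(index$mass)
  if (!n) return(list(first = 1L, count = 0L))
  first <- .lower_bound(index, lo)
  # first position with mass > hi: global bisection
  upper <- findInterval(hi, index$mass) + 1L
  list(first = first, count = max(0L, upper - first))
}

#' Retrieve in-window index terms as a table
#'
#' Convenience wrapper around [query_mass_range()] returning the matching
#' terms (with peptide sequences when the database is attached).
#'
#' @inheritParams query_mass_range
#' @return Tibble like [tidy.peptide_index()], restricted to the window.
#' @export
query_peptides <- function(index, lo, hi) {
  sl <- query_mass_range(index, lo, hi)
  if (!sl$count) {
    out <- tibble::tibble(mass = numeric(), protein_id = integer(),
                          start = integer(), length = integer())
    if (!is.null(index$proteins)) out$peptide <- character()
    return(out)
  }
  pos <- sl$first:(sl$first + sl$count - 1L)
  out <- tibble::tibble(mass = index$mass[pos], protein_id = index$protein_id[pos],
                        start = index$start[pos], length = index$length[pos])
  if (!is.null(index$proteins)) out$peptide <- peptide_sequences(index$proteins, out)
  out
}

#' Mass histogram of an index
#'
#' Bins the index masses into `[k w, (k+1) w)` intervals. The counts always
#' partition the index (their sum equals the term count).
#'
#' @param index A `peptide_index`.
#' @param bin_width Bin width in Daltons (> 0).
#' @return Tibble with `bin_lower` (Da) and `count`, one row per non-empty or
#'   in-range bin.
#' @export
index_mass_histogram <- function(index, bin_width = 100) {
  stopifnot(bin_width > 0)
  if (!length(index$mass)) {
    return(tibble::tibble(bin_lower = numeric(), count = integer()))
  }
  k <- floor(index$mass / bin_width)
  tb <- table(k)
  tibble::tibble(bin_lower = as.numeric(names(tb)) * bin_width,
                 count = as.integer(tb))
}

#' Fraction of index terms at or below a mass threshold
#'
#' The index-side analogue of the query-concentration statistic: what share of
#' the database lies within a given precursor mass. Computed through
#' [query_mass_range()].
#'
#' @param index A non-empty `peptide_index`.
#' @param threshold Mass threshold in Daltons.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_below <- function(index, threshold) {
  n <- length(index$mass)
  if (!n) stop("fraction_below is undefined for an empty index", call. = FALSE)
  lo <- min(index$params$min_mass, index$mass[1L])
  if (threshold < lo) return(0)
  query_mass_range(index, lo, threshold)$count / n
}
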