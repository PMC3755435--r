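# Closed and open (two-stage mass-delta) identification of spectra against a
# peptide index.
#
# Closed search retrieves the index slice within the precursor tolerance and
# scores every candidate unmodified. Open search widens the retrieval window
# by the allowed delta range, anchors candidates through their unmodified
# fragments (stage 1: the fragment series on the unshifted side of a
# modification still matches, which both localises one terminus and prunes the
# candidate list), then explains each survivor's residual precursor mass
# difference as a modification looked up in the inverted delta index, rescoring
# every sequence-compatible site (stage 2).
#
# The per-spectrum workers at the bottom operate on plain vectors (id, neutral
# mass, peak matrix) rather than tibble rows: a partitioned run visits every
# (spectrum, block) pair, so constant per-call overhead dominates wall time.

#' Search parameters
#'
#' @param precursor_tol Precursor tolerance (value in `precursor_tol_unit`).
#' @param precursor_tol_unit `"ppm"` (of the observed neutral mass) or `"da"`.
#' @param fragment_tol Fragment match tolerance, Daltons.
#' @param open_delta_range Signed interval of precursor mass differences
#'   considered in open mode, Daltons.
#' @param mod_match_tol Tolerance for matching a mass difference to a
#'   modification record, Daltons; differences within this of zero are treated
#'   as unmodified.
#' @param top_k Matches kept per spectrum.
#' @param min_matched_peaks Candidates with fewer unmodified fragment matches
#'   are discarded.
#' @return An object of class `search_params`.
#' @export
search_params <- function(precursor_tol = 10, precursor_tol_unit = c("ppm", "da"),
                          fragment_tol = 0.02, open_delta_range = c(-200, 500),
                          mod_match_tol = 0.01, top_k = 5L,
                          min_matched_peaks = 2L) {
  precursor_tol_unit <- match.arg(precursor_tol_unit)
  stopifnot(precursor_tol > 0, fragment_tol > 0, mod_match_tol > 0, top_k >= 1,
            length(open_delta_range) == 2L,
            open_delta_range[1L] <= open_delta_range[2L])
  structure(list(precursor_tol = precursor_tol,
                 precursor_tol_unit = precursor_tol_unit,
                 fragment_tol = fragment_tol,
                 open_delta_range = as.numeric(open_delta_range),
                 mod_match_tol = mod_match_tol,
                 top_k = as.integer(top_k),
                 min_matched_peaks = as.integer(min_matched_peaks)),
            class = "search_params")
}

.precursor_tol_da <- function(params, M) {
  if (params$precursor_tol_unit == "ppm") params$precursor_tol * M / 1e6
  else params$precursor_tol
}

.PSM_COLS <- c("spectrum_id", "rank", "protein_id", "accession", "start",
               "length", "peptide", "score", "matched_peaks",
               "precursor_delta", "mod_id", "mod_site", "flag")

.empty_psms_template <- NULL

.empty_psms <- function() {
  if (is.null(.empty_psms_template)) {
    tpl <- tibble::tibble(spectrum_id = character(), rank = integer(),
                          protein_id = integer(), accession = character(),
                          start = integer(), length = integer(),
                          peptide = character(), score = numeric(),
                          matched_peaks = integer(),
                          precursor_delta = numeric(), mod_id = character(),
                          mod_site = integer(), flag = character())
    utils::assignInMyNamespace(".empty_psms_template", tpl)
  }
  .empty_psms_template
}

#' Score a peptide against a spectrum
#'
#' Greedy one-to-one matching of theoretical b/y fragments to observed peaks:
#' fragments are taken in ascending m/z order and each is paired with the
#' closest unused peak within `fragment_tol` (ties to the lower m/z peak).
#' The score is `matched_peaks + matched_intensity / total_intensity`, so the
#' integer part counts matched fragments and the fractional part breaks ties
#' by explained intensity.
#'
#' @param spectrum One-row spectrum tibble.
#' @param peptide Candidate peptide sequence.
#' @param mod_delta,mod_site Optional modification (delta Da, 1-based site).
#' @param fragment_tol Fragment tolerance, Daltons.
#' @return List with `score` and `matched_peaks`.
#' @export
score_psm <- function(spectrum, peptide, mod_delta = NULL, mod_site = NULL,
                      fragment_tol = 0.02) {
  pk <- spectrum$peaks[[1L]]
  frags <- theoretical_fragments(peptide, mod_delta, mod_site)
  .score_peaks(pk[, 1L], pk[, 2L], frags, fragment_tol)
}

# Exact greedy scorer on raw arrays (peak_mz sorted ascending).
.score_peaks <- function(peak_mz, peak_int, frags, fragment_tol) {
  np <- length(peak_mz)
  if (!np || !length(frags)) return(list(score = 0, matched_peaks = 0L))
  total_int <- sum(peak_int)
  lo_idx <- findInterval(frags - fragment_tol, peak_mz, left.open = TRUE)
  hi_idx <- findInterval(frags + fragment_tol, peak_mz)
  used <- logical(np)
  matched <- 0L; mint <- 0
  for (k in seq_along(frags)) {
    a <- lo_idx[k] + 1L
    if (a > hi_idx[k]) next
    cand <- a:hi_idx[k]
    cand <- cand[!used[cand]]
    if (!length(cand)) next
    j <- cand[which.min(abs(peak_mz[cand] - frags[k]))]
    used[j] <- TRUE
    matched <- matched + 1L
    mint <- mint + peak_int[j]
  }
  frac <- if (total_int > 0) mint / total_int else 0
  list(score = matched + frac, matched_peaks = matched)
}

# Vectorised upper bound on the greedy match count for many candidate
# peptides at once: the number of b/y fragments having any observed peak
# within tolerance. Never smaller than the greedy one-to-one count, so it can
# prune candidates that cannot reach min_matched_peaks without changing which
# candidates survive exact filtering.
.batch_match_upper <- function(peptides, peak_mz, fragment_tol) {
  ncand <- length(peptides)
  if (!ncand) return(integer())
  if (!length(peak_mz)) return(integer(ncand))
  lens <- nchar(peptides)
  m <- .residue_mass_by_code[utf8ToInt(paste(peptides, collapse = ""))]
  cm <- c(0, cumsum(m))
  ends <- cumsum(lens); starts <- ends - lens
  proton <- mass_constants[["proton"]]; water <- mass_constants[["water"]]
  nfrag <- lens - 1L
  pep_of <- rep.int(seq_len(ncand), nfrag)
  i <- sequence(nfrag)
  prefix <- cm[starts[pep_of] + i + 1L] - cm[starts[pep_of] + 1L]
  total <- (cm[ends + 1L] - cm[starts + 1L])[pep_of]
  b <- prefix + proton
  y <- total - prefix + water + proton
  hit <- function(x) {
    findInterval(x + fragment_tol, peak_mz) >
      findInterval(x - fragment_tol, peak_mz, left.open = TRUE)
  }
  tabulate(pep_of[hit(b)], nbins = ncand) + tabulate(pep_of[hit(y)], nbins = ncand)
}

# Global PSM ordering: score desc, |precursor_delta| asc, then entry order.
.rank_psms <- function(df, top_k) {
  n <- nrow(df)
  if (!n) return(.empty_psms())
  o <- order(-df$score, abs(df$precursor_delta), df$protein_id, df$start,
             df$length, method = "radix")
  if (length(o) > top_k) o <- o[seq_len(top_k)]
  df <- df[o, ]
  df$rank <- seq_along(o)
  df[, .PSM_COLS]
}

.require_attached_db <- function(index) {
  if (is.null(index$proteins)) {
    stop("index has no attached protein database; pass `proteins` to load_index()",
         call. = FALSE)
  }
}

# Candidate slice for [lo, hi] as plain vectors (no tibble overhead).
.candidates <- function(index, lo, hi) {
  sl <- query_mass_range(index, lo, hi)
  if (!sl$count) return(NULL)
  pos <- sl$first:(sl$first + sl$count - 1L)
  pid <- index$protein_id[pos]
  start <- index$start[pos]
  len <- index$length[pos]
  list(mass = index$mass[pos], protein_id = pid, start = start, length = len,
       peptide = substr(index$proteins$sequence[pid + 1L], start + 1L,
                        start + len))
}

.new_psm_tbl <- function(sid, n, pid, accession, start, len, peptide, score,
                         matched, pdelta, mod_id, mod_site, flag) {
  tibble::new_tibble(list(
    spectrum_id = rep.int(sid, n), rank = integer(n) , protein_id = pid,
    accession = accession, start = start, length = len, peptide = peptide,
    score = score, matched_peaks = matched, precursor_delta = pdelta,
    mod_id = mod_id, mod_site = mod_site, flag = flag), nrow = n)
}

# Closed-mode worker on primitives.
.search_one_closed <- function(sid, M, peaks, index, params) {
  tol <- .precursor_tol_da(params, M)
  cand <- .candidates(index, M - tol, M + tol)
  if (is.null(cand)) return(.empty_psms())
  peak_mz <- peaks[, 1L]; peak_int <- peaks[, 2L]
  nc <- length(cand$mass)
  score <- numeric(nc); matched <- integer(nc)
  for (i in seq_len(nc)) {
    sc <- .score_peaks(peak_mz, peak_int, theoretical_fragments(cand$peptide[i]),
                       params$fragment_tol)
    score[i] <- sc$score; matched[i] <- sc$matched_peaks
  }
  keep <- matched >= params$min_matched_peaks
  if (!any(keep)) return(.empty_psms())
  df <- .new_psm_tbl(sid, sum(keep), cand$protein_id[keep],
                     index$proteins$accession[cand$protein_id[keep] + 1L],
                     cand$start[keep], cand$length[keep], cand$peptide[keep],
                     score[keep], matched[keep], M - cand$mass[keep],
                     rep.int(NA_character_, sum(keep)),
                     rep.int(NA_integer_, sum(keep)),
                     rep.int("", sum(keep)))
  .rank_psms(df, params$top_k)
}

# Open-mode worker on primitives (two-stage).
.search_one_open <- function(sid, M, peaks, index, mindex, params) {
  cand <- .candidates(index, M - params$open_delta_range[2L],
                      M - params$open_delta_range[1L])
  if (is.null(cand)) return(.empty_psms())
  peak_mz <- peaks[, 1L]; peak_int <- peaks[, 2L]
  # stage 1: unmodified-fragment anchoring (vectorised prune, then exact)
  upper <- .batch_match_upper(cand$peptide, peak_mz, params$fragment_tol)
  keep <- upper >= params$min_matched_peaks
  if (!any(keep)) return(.empty_psms())
  for (f in names(cand)) cand[[f]] <- cand[[f]][keep]
  nc <- length(cand$mass)
  score <- numeric(nc); matched <- integer(nc)
  for (i in seq_len(nc)) {
    sc <- .score_peaks(peak_mz, peak_int, theoretical_fragments(cand$peptide[i]),
                       params$fragment_tol)
    score[i] <- sc$score; matched[i] <- sc$matched_peaks
  }
  keep <- matched >= params$min_matched_peaks
  if (!any(keep)) return(.empty_psms())
  for (f in names(cand)) cand[[f]] <- cand[[f]][keep]
  score <- score[keep]; matched <- matched[keep]
  nc <- length(cand$mass)
  # stage 2: explain the residual precursor delta
  prot_len <- nchar(index$proteins$sequence)
  delta <- M - cand$mass
  mod_id <- rep.int(NA_character_, nc); mod_site <- rep.int(NA_integer_, nc)
  pdelta <- delta; flag <- rep.int("", nc)
  for (i in seq_len(nc)) {
    if (abs(delta[i]) <= params$mod_match_tol) next
    hits <- query_mod_by_delta(mindex, delta[i], params$mod_match_tol)
    best <- NULL
    if (nrow(hits)) {
      pep <- cand$peptide[i]
      at_n <- cand$start[i] == 0L
      at_c <- cand$start[i] + cand$length[i] == prot_len[cand$protein_id[i] + 1L]
      for (h in seq_len(nrow(hits))) {
        for (s in compatible_sites(pep, hits$sites[[h]], at_n, at_c)) {
          sc <- .score_peaks(peak_mz, peak_int,
                             theoretical_fragments(pep, hits$delta_mass[h], s),
                             params$fragment_tol)
          if (is.null(best) || sc$score > best$score) {
            best <- list(score = sc$score, matched_peaks = sc$matched_peaks,
                         mod_id = hits$mod_id[h],
                         mod_delta = hits$delta_mass[h], site = s)
          }
        }
      }
    }
    if (is.null(best)) {
      flag[i] <- "unexplained-delta"
    } else {
      score[i] <- best$score
      matched[i] <- best$matched_peaks
      pdelta[i] <- delta[i] - best$mod_delta
      mod_id[i] <- best$mod_id
      mod_site[i] <- best$site
    }
  }
  df <- .new_psm_tbl(sid, nc, cand$protein_id,
                     index$proteins$accession[cand$protein_id + 1L],
                     cand$start, cand$length, cand$peptide, score, matched,
                     pdelta, mod_id, mod_site, flag)
  .rank_psms(df, params$top_k)
}

#' Closed search of one spectrum
#'
#' Retrieves the index slice within the precursor tolerance of the observed
#' neutral mass and scores every candidate unmodified. Candidates with fewer
#' than `min_matched_peaks` matches are dropped; the rest are ranked by score
#' (descending), then absolute precursor delta, then entry order, and the top
#' `top_k` returned.
#'
#' @param spectrum One-row spectrum tibble.
#' @param index A `peptide_index` with its database attached.
#' @param params A [search_params()].
#' @return PSM tibble (possibly empty) with columns `spectrum_id`, `rank`,
#'   `protein_id`, `accession`, `start` (0-based), `length`, `peptide`,
#'   `score`, `matched_peaks`, `precursor_delta`, `mod_id`, `mod_site`
#'   (1-based), `flag`.
#' @export
search_spectrum_closed <- function(spectrum, index, params = search_params()) {
  .require_attached_db(index)
  .search_one_closed(spectrum$spectrum_id[1L], neutral_mass(spectrum)[1L],
                     spectrum$peaks[[1L]], index, params)
}

#' Open (two-stage) search of one spectrum
#'
#' Stage 1 retrieves every peptide whose mass differs from the observed
#' neutral mass by a delta inside `open_delta_range`, scores each by
#' unmodified fragment matching (the unshifted ion series anchors one
#' terminus), and keeps candidates reaching `min_matched_peaks`. Stage 2
#' computes each survivor's residual delta: within `mod_match_tol` of zero it
#' is reported unmodified; otherwise the delta is looked up in the inverted
#' modification index and every sequence-compatible site of every matching
#' modification is rescored with shifted fragments, keeping the best (ties:
#' closer delta-mass modification, then smaller site). A delta matching no
#' modification record is reported unmodified with flag `unexplained-delta`.
#' Unmodified and modified interpretations compete on score in the final
#' ranking.
#'
#' @inheritParams search_spectrum_closed
#' @param mindex A `mod_index`.
#' @return PSM tibble as in [search_spectrum_closed()].
#' @export
search_spectrum_open <- function(spectrum, index, mindex,
                                 params = search_params()) {
  .require_attached_db(index)
  .search_one_open(spectrum$spectrum_id[1L], neutral_mass(spectrum)[1L],
                   spectrum$peaks[[1L]], index, mindex, params)
}

#' Search a batch of spectra
#'
#' Applies closed or open per-spectrum search to every row; the output is
#' ordered by `spectrum_id` (then rank) and is therefore independent of the
#' input spectrum order. A per-spectrum error does not abort the batch: it
#' produces a flagged row.
#'
#' @param spectra Spectrum tibble.
#' @param index A `peptide_index` with its database attached.
#' @param mindex A `mod_index` (open mode only).
#' @param params A [search_params()].
#' @param mode `"closed"` or `"open"`.
#' @return PSM tibble.
#' @export
search_batch <- function(spectra, index, mindex = NULL,
                         params = search_params(),
                         mode = c("closed", "open")) {
  mode <- match.arg(mode)
  if (mode == "open" && is.null(mindex)) {
    stop("open search requires a modification index", call. = FALSE)
  }
  .require_attached_db(index)
  ids <- spectra$spectrum_id
  Ms <- if (nrow(spectra)) neutral_mass(spectra) else numeric()
  out <- vector("list", nrow(spectra))
  for (i in seq_len(nrow(spectra))) {
    out[[i]] <- tryCatch({
      if (mode == "closed") {
        .search_one_closed(ids[i], Ms[i], spectra$peaks[[i]], index, params)
      } else {
        .search_one_open(ids[i], Ms[i], spectra$peaks[[i]], index, mindex, params)
      }
    }, error = function(e) {
      row <- .empty_psms()[1, ]
      row$spectrum_id <- ids[i]
      row$flag <- paste0("error: ", conditionMessage(e))
      row
    })
  }
  df <- dplyr::bind_rows(out)
  df[order(df$spectrum_id, df$rank, method = "radix"), ]
}

#' Write a PSM table as TSV
#'
#' Start positions and modification sites are written 1-based; the in-memory
#' table keeps the index convention (0-based `start`).
#'
#' @param psms PSM tibble.
#' @param path Output path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_psms <- function(psms, path) {
  out <- psms
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
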