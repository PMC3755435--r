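# Load-balanced partitioning of the database and the spectra, and
# multi-worker search whose merged output is identical to the monolithic run.
#
# The database is split into contiguous parts balanced by amino-acid count
# (the digestion work per protein is driven by its residue count, not the
# record count). Spectra are sorted by neutral mass and cut into near-equal
# chunks, so spectra of close mass land in the same subtask and hit the same
# region of the mass-sorted index. Each part's index may be further split
# into blocks bounded by a memory cap; per-spectrum results from all blocks
# are merged under the global ranking rule, which makes the partitioned
# search provably equivalent to the single-index search.

#' Partition proteins by amino-acid count
#'
#' Contiguous partition balanced on residue totals. The partition is found by
#' a window-feasibility search: starting from the minimax part sum (binary
#' search over a greedy filler), the smallest maximum `M` is located such that
#' the proteins split into `n_parts` contiguous parts whose residue totals all
#' lie in `[M - L, M]`, where `L` is the longest single protein -- so the
#' imbalance between parts is bounded by `L`. The feasibility test is a
#' vectorised reachability scan over prefix sums, O(n_parts * P) per
#' candidate `M`. For very large databases (where the per-part protein count
#' makes imbalance negligible) a greedy assignment against the adaptive
#' target `ceiling(remaining_residues / remaining_parts)`, followed by local
#' boundary refinement, is used instead.
#'
#' @param proteins Protein tibble.
#' @param n_parts Number of parts (>= 1). When larger than the protein count,
#'   one singleton part per protein is returned with a warning.
#' @return Tibble with one row per part: `part`, `first_protein`,
#'   `last_protein` (0-based inclusive protein-ID range), `n_proteins`,
#'   `residues`.
#' @export
partition_by_amino_acids <- function(proteins, n_parts) {
  stopifnot(n_parts >= 1)
  P <- nrow(proteins)
  if (!P) stop("cannot partition an empty database", call. = FALSE)
  if (n_parts > P) {
    warning(sprintf("n_parts (%d) exceeds protein count (%d); using singleton parts",
                    n_parts, P), call. = FALSE)
    n_parts <- P
  }
  n_parts <- as.integer(n_parts)
  lens <- nchar(proteins$sequence)
  part <- NULL
  if (n_parts > 1L && P <= 5000L && max(lens) <= 20000L) {
    part <- .window_partition(lens, n_parts)
  }
  if (is.null(part)) {
    part <- .refine_cuts(.greedy_partition(lens, n_parts), lens, n_parts)
  }
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(part = part, pid = proteins$protein_id,
                                   len = lens), part),
    first_protein = min(pid), last_protein = max(pid),
    n_proteins = dplyr::n(), residues = sum(len), .groups = "drop")
}

#' Sort spectra by mass and split into chunks
#'
#' Spectra are sorted by neutral precursor mass (ties by `spectrum_id`) and
#' cut into `n_chunks` contiguous chunks of near-equal count (the first
#' `n %% n_chunks` chunks get one extra spectrum). Concatenating the chunks
#' reproduces the globally mass-sorted order.
#'
#' @param spectra Spectrum tibble.
#' @param n_chunks Number of chunks (>= 1).
#' @return Tibble with `chunk` and `spectrum_id`, in plan order; masses are
#'   non-decreasing within and across chunks.
#' @export
sort_and_chunk_spectra <- function(spectra, n_chunks) {
  stopifnot(n_chunks >= 1)
  n <- nrow(spectra)
  n_chunks <- as.integer(min(n_chunks, max(n, 1L)))
  o <- order(neutral_mass(spectra), spectra$spectrum_id, method = "radix")
  sizes <- rep.int(n %/% n_chunks, n_chunks)
  extra <- n %% n_chunks
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tibble::tibble(chunk = rep.int(seq_len(n_chunks), sizes),
                 spectrum_id = spectra$spectrum_id[o])
}

# Greedy contiguous assignment against an adaptive residue target; closes a
# part when adding the next protein would overshoot further than stopping, or
# when exactly enough proteins remain to keep every later part non-empty.
.greedy_partition <- function(lens, n_parts) {
  P <- length(lens)
  if (n_parts == 1L) return(rep.int(1L, P))
  total <- sum(lens)
  part <- integer(P)
  cur_part <- 1L; cur_sum <- 0L; assigned <- 0L
  target <- ceiling(total / n_parts)
  for (i in seq_len(P)) {
    remaining <- P - i + 1L
    unstarted <- n_parts - cur_part
    close <- cur_part < n_parts && cur_sum > 0L &&
      (remaining == unstarted ||
         abs(cur_sum + lens[i] - target) >= abs(cur_sum - target))
    if (close) {
      cur_part <- cur_part + 1L; cur_sum <- 0L
      target <- ceiling((total - assigned) / (n_parts - cur_part + 1L))
    }
    part[i] <- cur_part
    cur_sum <- cur_sum + lens[i]
    assigned <- assigned + lens[i]
  }
  part
}

# Exact bounded-imbalance partition. Finds the smallest maximum part sum M
# (starting at the minimax value) such that a contiguous n-part split exists
# with every part sum in [M - L, M], L = max(lens); reconstructs and returns
# it. Returns NULL if no such M exists within the scanned range (the caller
# then falls back to the greedy).
.window_partition <- function(lens, n_parts) {
  P <- length(lens)
  L <- max(lens)
  pre <- c(0, cumsum(as.numeric(lens)))  # pre[i + 1] = residues in first i
  # minimax part sum by binary search over a greedy feasibility filler
  fits <- function(M) {
    p <- 1L; cur <- 0
    for (i in seq_len(P)) {
      if (lens[i] > M) return(FALSE)
      if (cur > 0 && (cur + lens[i] > M || (P - i) < (n_parts - p))) {
        p <- p + 1L; cur <- 0
        if (p > n_parts) return(FALSE)
      }
      cur <- cur + lens[i]
    }
    TRUE
  }
  lo <- L; hi <- sum(lens)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (fits(mid)) hi <- mid else lo <- mid + 1
  }
  idx <- seq_len(P + 1L)
  for (M in lo:(lo + 2L * L)) {
    wlo <- max(1, M - L)
    # reach[[j]][i + 1]: first i proteins split into j parts, sums in [wlo, M]
    reach <- vector("list", n_parts + 1L)
    reach[[1L]] <- c(TRUE, rep.int(FALSE, P))
    for (j in seq_len(n_parts)) {
      cum0 <- c(0L, cumsum(reach[[j]]))
      # predecessors i' of i: pre[i' + 1] in [pre[i + 1] - M, pre[i + 1] - wlo]
      first <- findInterval(pre - M, pre, left.open = TRUE) + 1L
      last <- pmin(findInterval(pre - wlo, pre), idx - 1L)
      any_prev <- last >= first & (cum0[pmax(last, 0L) + 1L] - cum0[first]) > 0L
      reach[[j + 1L]] <- as.logical(any_prev)
    }
    if (isTRUE(reach[[n_parts + 1L]][P + 1L])) {
      # backtrack: deterministic smallest valid predecessor at each step
      cuts <- integer(n_parts + 1L); cuts[n_parts + 1L] <- P
      i <- P
      for (j in n_parts:1L) {
        s <- pre[i + 1L] - pre
        valid <- which(reach[[j]] & s >= wlo & s <= M & idx <= i)
        i <- valid[1L] - 1L
        cuts[j] <- i
      }
      return(rep.int(seq_len(n_parts), diff(cuts)))
    }
  }
  NULL
}

# Hill-climb on part boundaries: move one protein across a boundary whenever
# that strictly reduces (max - min, then max) of the part residue totals.
# Deterministic: boundaries are scanned in order and the first improving move
# is taken.
.refine_cuts <- function(part, lens, n_parts) {
  if (n_parts < 2L) return(part)
  cuts <- c(0L, cumsum(tabulate(part, n_parts)))  # part j = (cuts[j], cuts[j+1]]
  prefix <- c(0L, cumsum(lens))
  sums <- prefix[cuts[-1L] + 1L] - prefix[cuts[-(n_parts + 1L)] + 1L]
  obj <- function(s) c(max(s) - min(s), max(s))
  better <- function(a, b) a[1L] < b[1L] || (a[1L] == b[1L] && a[2L] < b[2L])
  for (iter in seq_len(10L * n_parts + 100L)) {
    improved <- FALSE
    for (j in 2L:n_parts) {
      for (d in c(-1L, 1L)) {
        nc <- cuts[j] + d
        if (nc <= cuts[j - 1L] || nc >= cuts[j + 1L]) next
        ns <- sums
        moved <- prefix[max(cuts[j], nc) + 1L] - prefix[min(cuts[j], nc) + 1L]
        ns[j - 1L] <- sums[j - 1L] + d * moved
        ns[j] <- sums[j] - d * moved
        if (better(obj(ns), obj(sums))) {
          cuts[j] <- nc; sums <- ns; improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  rep.int(seq_len(n_parts), diff(cuts))
}

# Split a sorted index into mass-contiguous blocks of at most `cap` entries,
# each a standalone peptide_index over the same database.
.index_blocks <- function(index, cap) {
  n <- length(index$mass)
  if (!is.finite(cap)) cap <- n
  cap <- max(1L, as.integer(min(cap, n)))
  if (!n) return(list(index))
  starts <- seq(1L, n, by = cap)
  lapply(starts, function(s) {
    e <- min(s + cap - 1L, n)
    blk <- new_peptide_index(mass = index$mass[s:e],
                             protein_id = index$protein_id[s:e],
                             start = index$start[s:e],
                             length = index$length[s:e],
                             params = index$params,
                             fingerprint = index$fingerprint,
                             proteins = index$proteins)
    blk
  })
}

# Merge per-spectrum PSM tables from several blocks under the global ranking.
.merge_block_psms <- function(tables, top_k) {
  df <- dplyr::bind_rows(tables)
  if (!nrow(df)) return(.empty_psms())
  out <- lapply(split(df, df$spectrum_id), .rank_psms, top_k = top_k)
  dplyr::bind_rows(out)
}

#' Partitioned multi-worker search
#'
#' Runs the full identification workflow under the distribution scheme: the
#' database is partitioned by amino-acid count into `n_parts` contiguous
#' parts; one mass-sorted index is built per part and split into blocks of at
#' most `memory_cap` entries; spectra are mass-sorted and cut into one chunk
#' per worker, assigned statically; every worker searches its chunk against
#' every block, and per-spectrum results are merged under the global ranking
#' rule. When `prefetch` is `TRUE` each part's next block is prepared in a
#' background fork while the current block is searched; the result is
#' identical either way, and identical -- PSM set and ranking -- to the
#' monolithic [search_batch()] over one index of the whole database.
#'
#' @param proteins Protein tibble.
#' @param spectra Spectrum tibble.
#' @param digestion A [digestion_params()].
#' @param params A [search_params()].
#' @param mindex A `mod_index` (open mode).
#' @param mode `"closed"` or `"open"`.
#' @param n_workers Number of worker processes (static chunk assignment).
#' @param n_parts Number of database parts.
#' @param memory_cap Maximum index entries held per block.
#' @param prefetch Prepare the next block concurrently with searching the
#'   current one.
#' @return PSM tibble ordered by `spectrum_id`, identical to the monolithic
#'   search.
#' @export
parallel_search <- function(proteins, spectra, digestion = digestion_params(),
                            params = search_params(), mindex = NULL,
                            mode = c("closed", "open"), n_workers = 1L,
                            n_parts = 1L, memory_cap = Inf, prefetch = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_workers >= 1, memory_cap >= 1)
  if (!nrow(spectra)) return(.empty_psms())
  plan <- partition_by_amino_acids(proteins, n_parts)
  chunk_plan <- sort_and_chunk_spectra(spectra, n_workers)
  chunk_ids <- split(chunk_plan$spectrum_id, chunk_plan$chunk)
  blocks <- list()
  for (p in seq_len(nrow(plan))) {
    sub <- proteins[proteins$protein_id >= plan$first_protein[p] &
                      proteins$protein_id <= plan$last_protein[p], ]
    part_index <- build_index(sub, digestion)
    # keep the full database attached so accessions and protein termini are
    # resolved identically to the monolithic run
    part_index$proteins <- proteins
    part_index$fingerprint <- db_fingerprint(proteins)
    blocks <- c(blocks, .index_blocks(part_index, memory_cap))
  }
  search_chunk <- function(chunk_spectra) {
    per_block <- vector("list", length(blocks))
    if (prefetch && length(blocks) > 1L &&
        requireNamespace("parallel", quietly = TRUE)) {
      # search block k while block k+1 is materialised in a background fork
      nxt <- parallel::mcparallel(blocks[[2L]])
      cur <- blocks[[1L]]
      for (k in seq_along(blocks)) {
        per_block[[k]] <- search_batch(chunk_spectra, cur, mindex, params, mode)
        if (k < length(blocks)) {
          cur <- parallel::mccollect(nxt)[[1L]]
          if (k + 1L < length(blocks)) {
            nxt <- parallel::mcparallel(blocks[[k + 2L]])
          }
        }
      }
    } else {
      for (k in seq_along(blocks)) {
        per_block[[k]] <- search_batch(chunk_spectra, blocks[[k]], mindex,
                                       params, mode)
      }
    }
    .merge_block_psms(per_block, params$top_k)
  }
  chunk_spectra <- lapply(chunk_ids, function(ids) {
    spectra[match(ids, spectra$spectrum_id), ]
  })
  results <- if (n_workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(chunk_spectra, search_chunk,
                       mc.cores = min(n_workers, length(chunk_spectra)))
  } else {
    lapply(chunk_spectra, search_chunk)
  }
  failed <- vapply(results, function(r) inherits(r, "try-error") ||
                     !is.data.frame(r), logical(1))
  if (any(failed)) {
    stop(sprintf("worker failure in spectrum chunk(s): %s",
                 paste(which(failed), collapse = ", ")), call. = FALSE)
  }
  df <- dplyr::bind_rows(results)
  df[order(df$spectrum_id, df$rank, method = "radix"), ]
}
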