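# FASTA protein database input/output and synthetic database generation.
#
# A protein database is represented as a tibble with one row per record:
#   protein_id  0-based ordinal in file order (the first of the three integers
#               making up an index term)
#   accession   first whitespace-delimited token of the header
#   description remainder of the header ("" when absent)
#   sequence    upper-cased residue string, '*' stripped, no whitespace

#' Read a FASTA protein database
#'
#' Parses a (possibly multi-line) amino-acid FASTA file into a protein tibble.
#' Protein IDs are assigned positionally: the n-th record in the file gets
#' `protein_id = n - 1`, matching the protein-ID component of index terms, and
#' are stable across re-reads of the same file. Sequence lines are
#' concatenated, internal whitespace removed, residues upper-cased and `'*'`
#' (stop codons) stripped.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `accession`, `description`,
#'   `sequence`, in file order. An empty file yields a zero-row tibble.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|TEST first test protein", "MKRPAK", "GGHILK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop(sprintf("input FASTA not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  seq_before_header <- which(nonblank & !is_header)
  if (length(seq_before_header) && (!any(is_header) ||
      seq_before_header[1L] < which(is_header)[1L])) {
    stop(sprintf("malformed FASTA: sequence data before any '>' header at line %d",
                 seq_before_header[1L]), call. = FALSE)
  }
  headers <- which(is_header)
  if (!length(headers)) {
    return(tibble::tibble(protein_id = integer(), accession = character(),
                          description = character(), sequence = character()))
  }
  header_text <- sub("^>", "", lines[headers])
  accession <- sub("\\s.*$", "", header_text)
  description <- ifelse(grepl("\\s", header_text),
                        trimws(sub("^\\S+\\s+", "", header_text)), "")
  # residues between consecutive headers
  grp <- cumsum(is_header)
  body <- !is_header & nonblank
  seqs <- vapply(split(lines[body], grp[body])[as.character(seq_along(headers))],
                 function(x) paste(x, collapse = ""), character(1))
  seqs[is.na(seqs)] <- ""
  seqs <- toupper(gsub("[*[:space:]]", "", seqs))
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop(sprintf("malformed FASTA: record '%s' (line %d) has no sequence lines",
                 accession[empty[1L]], headers[empty[1L]]), call. = FALSE)
  }
  tibble::tibble(protein_id = seq_along(headers) - 1L,
                 accession = accession,
                 description = unname(description),
                 sequence = unname(seqs))
}

#' Write a protein tibble to FASTA
#'
#' Sequences are wrapped at 60 columns. Headers are `>accession description`
#' (description omitted when empty). Writing then reading reproduces the
#' records exactly.
#'
#' @param proteins Protein tibble as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins))
  hdr <- ifelse(nzchar(proteins$description),
                paste0(">", proteins$accession, " ", proteins$description),
                paste0(">", proteins$accession))
  wrap <- function(s) {
    n <- nchar(s)
    substring(s, seq(1L, n, 60L), pmin(seq(1L, n, 60L) + 59L, n))
  }
  out <- unlist(purrr::map2(hdr, proteins$sequence, function(h, s) c(h, wrap(s))),
                use.names = FALSE)
  writeLines(if (is.null(out)) character() else out, path)
  invisible(path)
}

#' Generate a synthetic protein database
#'
#' Draws `n_proteins` random protein sequences with i.i.d. residues (uniform
#' over the 20 canonical amino acids unless `alphabet` is overridden) and
#' lengths uniform on `[min_length, max_length]`. Deterministic for a fixed
#' seed. Used to build test databases with known content; real databases have
#' strongly non-uniform residue composition, which this generator does not
#' emulate.
#'
#' @param n_proteins Number of records (>= 1).
#' @param min_length,max_length Inclusive protein length bounds (`min_length >= 3`).
#' @param seed Integer seed; the generator is a pure function of its arguments.
#' @param alphabet Character vector of residue letters to draw from.
#' @param path Optional path; when given the database is also written as FASTA.
#' @return Protein tibble (see [read_fasta()]) with accessions `SYNP000001`, ...
#' @examples
#' generate_synthetic_fasta(3, 10, 20, seed = 1)
#' @export
generate_synthetic_fasta <- function(n_proteins, min_length, max_length, seed,
                                     alphabet = .canonical_aa, path = NULL) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    stop("n_proteins must be >= 1", call. = FALSE)
  }
  if (min_length < 3 || max_length < min_length) {
    stop("invalid length bounds: need 3 <= min_length <= max_length", call. = FALSE)
  }
  proteins <- with_preserved_seed(seed, {
    lens <- sample.int(max_length - min_length + 1L, n_proteins, replace = TRUE) +
      min_length - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(alphabet, L, replace = TRUE), collapse = "")
    }, character(1))
    tibble::tibble(protein_id = seq_len(n_proteins) - 1L,
                   accession = sprintf("SYNP%06d", seq_len(n_proteins)),
                   description = sprintf("synthetic protein length=%d", lens),
                   sequence = seqs)
  })
  if (!is.null(path)) write_fasta(proteins, path)
  proteins
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Content fingerprint of a protein database: md5 over accessions and sequences.
# Used to detect searching against an index built from a different database.
db_fingerprint <- function(proteins) {
  digest::digest(paste(proteins$accession, proteins$sequence,
                       sep = "\t", collapse = "\n"),
                 algo = "md5", serialize = FALSE)
}
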