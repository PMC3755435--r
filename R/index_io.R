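# Binary on-disk format for the peptide index.
#
# All integers little-endian. Layout (offsets in bytes):
#
#   0            magic "OPEPIDX1" (8 ASCII bytes)
#   8            u32 version (currently 1)
#   12           u32 header_length H (byte offset of the mass array)
#   16           u32 n_records N
#   20           u32 digestion mode code (1 specific, 2 semispecific, 3 nonspecific)
#   24           u32 min_len;  28 u32 max_len;  32 u32 max_missed_cleavages
#   36           f64 min_mass; 44 f64 max_mass
#   52           i32 bucket_min; 56 u32 n_buckets B
#   60           enzyme cleave-after set, 26 bytes (residue letters, 0-padded)
#   86           enzyme suppress-next set, 26 bytes (0-padded)
#   112          enzyme side (1 byte: 'C' or 'N'); 113..115 padding (0)
#   116          database fingerprint, 32 ASCII hex bytes
#   148 = H      mass array: N x f64
#   H + 8N       entry array: N records of (u32 protein_id, u32 start, u32 length)
#                -- constant 12-byte terms; with the 8-byte mass key each
#                   record occupies 20 bytes total
#   H + 20N      bucket offset array: B x u64 (0-based first positions),
#                written as (lo, hi) u32 word pairs
#
# The header is fixed-width (H = 148 for version 1), so the entry array can be
# located by offset arithmetic alone. Total file size = H + 20 N + 8 B.

.INDEX_MAGIC <- "OPEPIDX1"
.INDEX_VERSION <- 1L
.INDEX_HEADER_BYTES <- 148L
.MODE_CODES <- c(specific = 1L, semispecific = 2L, nonspecific = 3L)

.pad_ascii <- function(s, width) {
  r <- utf8ToInt(s)
  if (length(r) > width) stop("field too long for fixed-width header", call. = FALSE)
  as.raw(c(r, rep.int(0L, width - length(r))))
}

.unpad_ascii <- function(raw) {
  raw <- raw[raw != as.raw(0L)]
  if (!length(raw)) return(character(0))
  strsplit(rawToChar(raw), "")[[1]]
}

.write_u32 <- function(con, x) {
  x <- as.numeric(x)
  if (any(x < 0 | x >= 2^31)) {
    stop("index field exceeds the serializable integer range", call. = FALSE)
  }
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

#' Save a peptide index
#'
#' Writes the documented fixed-width binary layout: a 148-byte header, the
#' mass array (8-byte doubles), the entry array (three 4-byte unsigned
#' integers per term: protein ID, start, length -- every term record the same
#' width), and the bucket offset table (8-byte unsigned). Loading reproduces
#' the index bit-exactly. The attached protein database is not serialized;
#' its fingerprint is, so [load_index()] can verify the database supplied at
#' search time.
#'
#' @param index A `peptide_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.INDEX_MAGIC), con)
  .write_u32(con, .INDEX_VERSION)
  .write_u32(con, .INDEX_HEADER_BYTES)
  .write_u32(con, length(index$mass))
  .write_u32(con, .MODE_CODES[[index$params$mode]])
  .write_u32(con, index$params$min_len)
  .write_u32(con, index$params$max_len)
  .write_u32(con, index$params$max_missed_cleavages)
  writeBin(as.numeric(c(index$params$min_mass, index$params$max_mass)), con,
           size = 8L, endian = "little")
  writeBin(as.integer(index$bucket_min), con, size = 4L, endian = "little")
  .write_u32(con, length(index$bucket_offsets))
  writeBin(.pad_ascii(paste(index$params$enzyme$cleave_after, collapse = ""), 26L), con)
  writeBin(.pad_ascii(paste(index$params$enzyme$suppress_next, collapse = ""), 26L), con)
  writeBin(.pad_ascii(index$params$enzyme$side, 4L), con)
  writeBin(.pad_ascii(index$fingerprint, 32L), con)
  writeBin(index$mass, con, size = 8L, endian = "little")
  n <- length(index$mass)
  if (n) {
    ent <- matrix(0L, nrow = 3L, ncol = n)
    ent[1L, ] <- index$protein_id
    ent[2L, ] <- index$start
    ent[3L, ] <- index$length
    if (any(ent < 0L)) stop("negative entry field", call. = FALSE)
    writeBin(as.integer(ent), con, size = 4L, endian = "little")
  }
  # u64 bucket offsets, 0-based, as (lo, hi) u32 pairs; hi is 0 below 2^32 terms
  off0 <- index$bucket_offsets - 1L
  words <- matrix(0L, nrow = 2L, ncol = length(off0))
  words[1L, ] <- off0
  writeBin(as.integer(words), con, size = 4L, endian = "little")
  invisible(path)
}

#' Load a peptide index
#'
#' Reads a file written by [save_index()] and reconstructs the index
#' bit-exactly. When `proteins` is supplied its fingerprint is checked against
#' the one stored in the header: a mismatch raises a stale-index warning and
#' the database is not attached.
#'
#' @param path Path to an index file.
#' @param proteins Optional protein tibble to attach for sequence recovery.
#' @return A `peptide_index`.
#' @export
load_index <- function(path, proteins = NULL) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, .INDEX_MAGIC)) {
    stop("not a peptide index file (bad magic)", call. = FALSE)
  }
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != .INDEX_VERSION) {
    stop(sprintf("unsupported index format version %d", version), call. = FALSE)
  }
  header_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  mode_code <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  min_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  max_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  max_mc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  mm <- readBin(con, "numeric", 2L, size = 8L, endian = "little")
  bucket_min <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n_buckets <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  cleave <- .unpad_ascii(readBin(con, "raw", 26L))
  suppress <- .unpad_ascii(readBin(con, "raw", 26L))
  side <- .unpad_ascii(readBin(con, "raw", 4L))
  fingerprint <- rawToChar(readBin(con, "raw", 32L))
  expected <- header_len + 20 * n + 8 * n_buckets
  if (is.na(size) || size != expected) {
    stop(sprintf("corrupt index file: %d bytes on disk, %d expected",
                 size, expected), call. = FALSE)
  }
  mass <- readBin(con, "numeric", n, size = 8L, endian = "little")
  ent <- readBin(con, "integer", 3L * n, size = 4L, endian = "little")
  if (length(mass) != n || length(ent) != 3L * n) {
    stop("corrupt index file: truncated arrays", call. = FALSE)
  }
  ent <- matrix(ent, nrow = 3L)
  words <- readBin(con, "integer", 2L * n_buckets, size = 4L, endian = "little")
  words <- matrix(words, nrow = 2L)
  offsets <- words[1L, ] + words[2L, ] * 2^32 + 1L
  params <- digestion_params(mode = names(.MODE_CODES)[match(mode_code, .MODE_CODES)],
                             enzyme = enzyme_rule(cleave, suppress,
                                                 side = paste(side, collapse = "")),
                             min_len = min_len, max_len = max_len,
                             min_mass = mm[1L], max_mass = mm[2L],
                             max_missed_cleavages = max_mc)
  attach <- NULL
  if (!is.null(proteins)) {
    if (!identical(db_fingerprint(proteins), fingerprint)) {
      warning("stale index: database fingerprint does not match the index header",
              call. = FALSE)
    } else {
      attach <- proteins
    }
  }
  idx <- new_peptide_index(mass = mass, protein_id = ent[1L, ], start = ent[2L, ],
                           length = ent[3L, ], params = params,
                           fingerprint = fingerprint, proteins = attach)
  idx$bucket_offsets <- as.integer(offsets)
  idx
}
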