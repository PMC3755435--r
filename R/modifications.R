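# Post-translational modification table and the inverted delta-mass index.
#
# A modification record is (mod_id, name, delta_mass, sites), where sites is a
# set of specifiers: a one-letter residue code, or one of the terminus
# specifiers "peptide-N", "peptide-C", "protein-N", "protein-C". The inverted
# index sorts records ascending by (delta_mass, mod_id) and carries a 1-Da
# bucket offset table so a mass-difference lookup is constant expected work.

#' Load a modification table
#'
#' Reads a tab-separated modification table with header columns `id`, `name`,
#' `delta_mass`, `sites` (sites comma-joined). The package ships a default
#' table of common modifications (oxidation, carbamidomethyl, phospho,
#' acetyl, methylations, deamidation, losses, ...) at
#' `system.file("extdata", "modifications.tsv", package = "openpept")`.
#'
#' @param path Path to a modification TSV; defaults to the shipped table.
#' @return Tibble with columns `mod_id`, `name`, `delta_mass` (signed Da,
#'   monoisotopic), `sites` (list of character vectors).
#' @export
load_modifications <- function(path = default_modifications_path()) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("id", "name", "delta_mass", "sites")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("modification table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  delta <- suppressWarnings(as.numeric(raw$delta_mass))
  if (anyNA(delta)) {
    stop(sprintf("unparseable delta_mass at line %d of %s",
                 which(is.na(delta))[1L] + 1L, path), call. = FALSE)
  }
  if (anyDuplicated(raw$id)) {
    dup <- raw$id[duplicated(raw$id)][1L]
    stop(sprintf("duplicate mod_id '%s' at line %d",
                 dup, max(which(raw$id == dup)) + 1L), call. = FALSE)
  }
  sites <- strsplit(raw$sites, ",", fixed = TRUE)
  sites <- lapply(sites, function(s) trimws(s[nzchar(trimws(s))]))
  if (any(!lengths(sites))) {
    stop(sprintf("empty sites field at line %d",
                 which(!lengths(sites))[1L] + 1L), call. = FALSE)
  }
  tibble::tibble(mod_id = raw$id, name = raw$name, delta_mass = delta,
                 sites = sites)
}

#' @rdname load_modifications
#' @export
default_modifications_path <- function() {
  system.file("extdata", "modifications.tsv", package = "openpept",
              mustWork = TRUE)
}

#' Build the inverted modification index
#'
#' Sorts modification records ascending by (delta_mass, mod_id) -- negative
#' deltas (losses) included -- and attaches a 1-Da bucket offset table over
#' the full signed delta range for constant-expected-work lookups.
#'
#' @param mods Modification tibble from [load_modifications()].
#' @return An object of class `mod_index`.
#' @export
build_mod_index <- function(mods = load_modifications()) {
  o <- order(mods$delta_mass, mods$mod_id, method = "radix")
  mods <- mods[o, ]
  bucket_min <- as.integer(floor(min(mods$delta_mass)))
  bucket_max <- as.integer(ceiling(max(mods$delta_mass)))
  b <- bucket_min:(bucket_max + 1L)
  offsets <- findInterval(b, mods$delta_mass, left.open = TRUE) + 1L
  structure(list(mods = mods, bucket_min = bucket_min,
                 bucket_offsets = as.integer(offsets)),
            class = "mod_index")
}

#' @export
print.mod_index <- function(x, ...) {
  cat(sprintf("<mod_index> %d modifications, delta %.4f to %.4f Da\n",
              nrow(x$mods), min(x$mods$delta_mass), max(x$mods$delta_mass)))
  invisible(x)
}

#' Look up modifications by mass difference
#'
#' Returns every modification whose delta mass lies within `tol` of the
#' observed mass difference, ranked by absolute distance ascending (ties by
#' `mod_id`). The first positions are found through the bucket table; a short
#' scan covers the tolerance window.
#'
#' @param mindex A `mod_index`.
#' @param delta Observed mass difference in Daltons (signed).
#' @param tol Tolerance; absolute Daltons by default.
#' @param unit `"da"` or `"ppm"` (ppm of `|delta|`).
#' @return Modification tibble with an extra `distance` column, possibly
#'   empty.
#' @export
query_mod_by_delta <- function(mindex, delta, tol = 0.01, unit = c("da", "ppm")) {
  unit <- match.arg(unit)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  tol_da <- if (unit == "ppm") tol * abs(delta) / 1e6 else tol
  dm <- mindex$mods$delta_mass
  lo <- delta - tol_da; hi <- delta + tol_da
  bmin <- mindex$bucket_min
  bmax <- bmin + length(mindex$bucket_offsets) - 2L
  b <- floor(lo)
  if (b >= bmin && b <= bmax) {
    p <- mindex$bucket_offsets[b - bmin + 1L]
    while (p <= length(dm) && dm[p] < lo) p <- p + 1L
    first <- p
  } else {
    first <- findInterval(lo, dm, left.open = TRUE) + 1L
  }
  last <- findInterval(hi, dm)
  if (last < first) {
    out <- mindex$mods[0, ]
    out$distance <- numeric()
    return(out)
  }
  out <- mindex$mods[first:last, ]
  out$distance <- abs(out$delta_mass - delta)
  out[order(out$distance, out$mod_id, method = "radix"), ]
}

# Positions (1-based) in `peptide` where a modification with site set `sites`
# may sit. Terminus specifiers map to the first/last residue; protein-level
# termini additionally require the peptide to touch the protein end.
compatible_sites <- function(peptide, sites, at_protein_n = FALSE,
                             at_protein_c = FALSE) {
  n <- nchar(peptide)
  chars <- strsplit(peptide, "")[[1]]
  pos <- integer()
  for (s in sites) {
    pos <- c(pos, switch(s,
      "peptide-N" = 1L,
      "peptide-C" = n,
      "protein-N" = if (at_protein_n) 1L else integer(),
      "protein-C" = if (at_protein_c) n else integer(),
      which(chars == s)))
  }
  sort(unique(pos))
}
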