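# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, linear scans) so they cannot share a bug
# with the implementation paths they check.

aa20 <- setdiff(names(residue_masses), "U")

# Residue-by-residue mass sum, independent of the package's cumulative-sum path.
oracle_mass <- function(peptide) {
  sum(residue_masses[strsplit(peptide, "")[[1]]]) + 18.010565
}

# All substrings with length and mass in the windows: naive double loop.
oracle_nonspecific <- function(sequence, min_len, max_len, min_mass, max_mass) {
  L <- nchar(sequence)
  out <- list()
  for (s in 0:(L - 1)) {
    for (k in min_len:min(max_len, L - s)) {
      pep <- substr(sequence, s + 1, s + k)
      if (grepl("[^A-Z]|[BJOXZ]", pep)) next
      m <- oracle_mass(pep)
      if (m >= min_mass && m <= max_mass) {
        out[[length(out) + 1]] <- data.frame(start = s, length = k, mass = m)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), length = integer(), mass = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$length), ]
}

# Linear-scan range query over the raw mass array.
oracle_slice <- function(index, lo, hi) {
  hit <- which(index$mass >= lo & index$mass <= hi)
  if (!length(hit)) list(first = NA_integer_, count = 0L)
  else list(first = hit[1], count = length(hit))
}

random_peptide <- function(n, alphabet = aa20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Entry-set key for containment comparisons.
entry_key <- function(df) sprintf("%d:%d:%d", df$protein_id, df$start, df$length)

# Re-rank a scored candidate table with the documented global ordering; used
# as the ranking oracle in brute-force search comparisons.
oracle_rank <- function(df, top_k) {
  o <- order(-df$score, abs(df$precursor_delta), df$protein_id, df$start,
             df$length)
  df <- df[head(o, top_k), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df
}
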