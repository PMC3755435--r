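# Plotting helpers: index and query mass distributions, PSM score overview.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the index mass distribution
#'
#' Bar chart of index term counts per mass bin (the index-side distribution:
#' typically heavy-tailed towards high mass under nonspecific digestion).
#'
#' @param object A `peptide_index`.
#' @param bin_width Bin width in Daltons.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peptide_index
#' @export
autoplot.peptide_index <- function(object, bin_width = 100, ...) {
  h <- index_mass_histogram(object, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lower + bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey30") +
    ggplot2::labs(x = "peptide mass (Da)", y = "index terms",
                  title = sprintf("Index mass distribution (%s digestion)",
                                  object$params$mode)) +
    ggplot2::theme_minimal()
}

#' Plot the query (precursor) mass distribution
#'
#' @param spectra Spectrum tibble.
#' @param bin_width Bin width in Daltons.
#' @return A ggplot object.
#' @export
plot_query_distribution <- function(spectra, bin_width = 100) {
  m <- neutral_mass(spectra)
  edges <- seq(floor(min(m) / bin_width) * bin_width,
               ceiling(max(m) / bin_width) * bin_width + bin_width,
               by = bin_width)
  h <- query_mass_distribution(spectra, edges)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "steelblue") +
    ggplot2::labs(x = "precursor neutral mass (Da)", y = "spectra",
                  title = "Query mass distribution") +
    ggplot2::theme_minimal()
}

#' Plot PSM score distribution by rank
#'
#' @param psms PSM tibble from [search_batch()].
#' @return A ggplot object.
#' @export
plot_psm_scores <- function(psms) {
  df <- psms[!is.na(psms$score), ]
  df$rank1 <- factor(ifelse(df$rank == 1L, "rank 1", "lower ranks"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$rank1)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "PSM score (matched peaks + intensity fraction)",
                  y = "PSMs", fill = NULL) +
    ggplot2::theme_minimal()
}
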