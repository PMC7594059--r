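#' Contig abundance as percent of non-rRNA reads
#'
#' @param read_count Reads assigned to the contig (0 <= count <= total).
#' @param total_non_rrna Library total of non-rRNA reads (> 0).
#' @return Percentage, rounded to 2 decimals.
#' @export
abundance <- function(read_count, total_non_rrna) {
  if (any(total_non_rrna <= 0)) stop("total_non_rrna must be positive")
  if (any(read_count < 0) || any(read_count > total_non_rrna))
    stop("read_count must lie in [0, total_non_rrna]")
  round(100 * read_count / total_non_rrna, 2)
}

#' Classify an abundance percentage
#'
#' Anchored at the two observed extremes for viral contigs: 0.01% of
#' non-rRNA reads is average abundance and 1.2% is very high; percentages
#' at or below 0.01 are `average`, at or above 1.2 `very_high`, anything
#' between `high`.
#'
#' @param percent Abundance percentage(s).
#' @return Character vector of classes.
#' @export
classify_abundance <- function(percent) {
  ifelse(percent <= 0.01, "average",
         ifelse(percent >= 1.2, "very_high", "high"))
}
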