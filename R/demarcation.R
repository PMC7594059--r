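#' Global pairwise amino-acid identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11 / extend 1);
#' identity is the fraction of identical columns over all alignment
#' columns after trimming terminal-gap columns. Internal gaps count as
#' mismatches.
#'
#' @param a,b Nonempty amino-acid strings.
#' @return Percent identity in [0, 100].
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  both <- which(pa != "-" & sa != "-")
  if (!length(both)) return(0)
  keep <- seq(min(both), max(both))  # trim terminal-gap columns
  100 * sum(pa[keep] == sa[keep] & pa[keep] != "-") / length(keep)
}

#' Pairwise-identity matrix over a sequence set
#'
#' @param seqs Named character vector of amino-acid sequences, or a
#'   data.frame with `id` and `seq`.
#' @return Square symmetric matrix of percent identities with a 100
#'   diagonal, dimnames from the input labels.
#' @export
identity_matrix <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  n <- length(seqs)
  if (!n) stop("no sequences")
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v <- global_identity(seqs[[i]], seqs[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Threshold clustering into species
#'
#' Single-linkage clustering of an identity matrix: any pair at or above
#' the demarcation threshold is linked, and connected components are the
#' species. Output clusters are ordered by first-seen label, making the
#' partition order-stable.
#'
#' @param matrix Identity matrix from [identity_matrix()].
#' @param threshold Percent identity demarcation threshold (90 is the
#'   common RdRp species criterion; 50 is used for narna-like viruses).
#' @return List of character vectors (the clusters).
#' @export
cluster_species <- function(matrix, threshold) {
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]")
  labels <- rownames(matrix)
  n <- length(labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && matrix[i, j] >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(labels, match(roots, unique(roots))) |> unname()
}

#' Place a query against intra/inter-rank identity distributions
#'
#' PASC-style rank placement: the query's identities to an established
#' reference taxon are compared with the identity distributions observed
#' within (`intra`) and between (`inter`) that rank's members. A query
#' whose best identity falls below every intra-rank sample is a new-genus
#' candidate; one reaching at least the 5% intra-rank quantile belongs to
#' an existing taxon; anything between is a new species within the rank.
#'
#' @param query_identities Percent identities of the query to the
#'   reference members.
#' @param intra,inter Nonempty percent-identity samples for the
#'   intra-rank and inter-rank distributions.
#' @param quantile Intra-rank quantile for the existing-taxon call
#'   (default 0.05).
#' @return List: `verdict` in `{existing_taxon, new_species,
#'   new_genus_candidate}` and a `summary` data.frame (min/median/max of
#'   the query, intra and inter distributions).
#' @export
place_rank <- function(query_identities, intra, inter, quantile = 0.05) {
  if (!length(intra) || !length(inter))
    stop("intra and inter identity samples must be nonempty")
  q_max <- max(query_identities)
  verdict <- if (q_max < min(intra)) "new_genus_candidate"
    else if (q_max >= stats::quantile(intra, quantile, names = FALSE))
      "existing_taxon"
    else "new_species"
  summ <- function(x) c(min = min(x), median = stats::median(x), max = max(x))
  list(verdict = verdict,
       summary = data.frame(
         distribution = c("query", "intra", "inter"),
         rbind(summ(query_identities), summ(intra), summ(inter)),
         stringsAsFactors = FALSE, row.names = NULL))
}

#' Neighbor-joining tree from an identity matrix
#'
#' Converts identities to distances (100 - identity) and runs standard
#' neighbor joining; on additive matrices the tree's path lengths
#' reproduce the input distances.
#'
#' @param matrix Identity matrix (or a distance matrix if
#'   `is_distance = TRUE`).
#' @param is_distance Set TRUE if `matrix` already holds distances.
#' @return Newick string (unrooted tree).
#' @export
nj_tree <- function(matrix, is_distance = FALSE) {
  d <- if (is_distance) matrix else 100 - matrix
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (n == 2) {
    return(sprintf("(%s:%g,%s:%g);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2))
  }
  tr <- ape::nj(stats::as.dist(d))
  ape::write.tree(tr)
}
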