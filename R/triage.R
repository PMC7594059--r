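#' Classify a contig into an evidence tier
#'
#' The four tiers partition a library by detectability: `strong_hit`
#' (best reference e-value < `e_strong`), `weak_hit` (e-value in
#' [`e_strong`, `e_weak`)), `orphan_long_orf` (no hit below `e_weak` but
#' at least one ORF of `min_aa` residues), and `dark_matter` (no signal
#' at all).
#'
#' @param contig_id Contig identifier.
#' @param reference_hits Hits for this contig from [search_reference()]
#'   (may be empty).
#' @param orfs ORFs for this contig (already gated at `min_aa`).
#' @param e_strong,e_weak Tier bounds (defaults 1e-05 and 1e-03).
#' @param min_aa Long-ORF gate in amino acids (default 200).
#' @return Tier string.
#' @export
classify_contig <- function(contig_id, reference_hits, orfs,
                            e_strong = 1e-5, e_weak = 1e-3, min_aa = 200) {
  best_e <- if (!is.null(reference_hits) && nrow(reference_hits))
    min(reference_hits$e_value) else Inf
  if (best_e < e_strong) return("strong_hit")
  if (best_e < e_weak) return("weak_hit")
  has_long <- !is.null(orfs) && nrow(orfs) &&
    any(nchar(orfs$aa_seq) >= min_aa)
  if (has_long) "orphan_long_orf" else "dark_matter"
}

#' Arbitrate an RdRp candidate against decoys
#'
#' Winner-takes-all by bit score across the union of viral profile hits,
#' decoy profile hits and reference hits: the contig is a candidate virus
#' iff the single best-scoring hit is viral (`rdrp_viral` profile or
#' `viral` reference target). Best hits to decoy profiles reject the
#' candidate; phage decoys record the reason `"phage-like"`.
#'
#' @param profile_hits Hits from [scan_orfs()] for this contig's ORFs.
#' @param reference_hits Hits from [search_reference()] for this contig.
#' @return List: `candidate` (logical), `reason` (string or `NA`),
#'   `best_class`, `best_name`, `best_score`.
#' @export
arbitrate_candidate <- function(profile_hits = NULL, reference_hits = NULL) {
  tab <- list()
  if (!is.null(profile_hits) && nrow(profile_hits))
    tab[[1]] <- data.frame(name = profile_hits$profile_name,
                           class = profile_hits$profile_class,
                           score = profile_hits$bit_score,
                           stringsAsFactors = FALSE)
  if (!is.null(reference_hits) && nrow(reference_hits))
    tab[[2]] <- data.frame(name = reference_hits$target_id,
                           class = reference_hits$target_label,
                           score = reference_hits$bit_score,
                           stringsAsFactors = FALSE)
  tab <- do.call(rbind, tab)
  if (is.null(tab) || !nrow(tab))
    return(list(candidate = FALSE, reason = "no hits",
                best_class = NA_character_, best_name = NA_character_,
                best_score = NA_real_))
  tab <- tab[order(-tab$score, tab$name), , drop = FALSE]
  best <- tab[1, ]
  viral <- best$class %in% c("rdrp_viral", "viral")
  reason <- if (viral) NA_character_
    else if (best$class == "decoy" && grepl("phage", best$name,
                                            ignore.case = TRUE))
      "phage-like"
    else paste0("best hit nonviral: ", best$name)
  if (!viral && best$class == "decoy" && !grepl("phage", best$name,
                                                ignore.case = TRUE))
    reason <- paste0("decoy best hit: ", best$name)
  list(candidate = viral, reason = reason, best_class = best$class,
       best_name = best$name, best_score = best$score)
}

#' Summarise tier counts and fractions
#'
#' @param tiers Character vector of tiers (one per contig).
#' @return data.frame with `tier`, `count`, `fraction`; all four tiers
#'   always present. Zero rows for empty input.
#' @export
summarize_tiers <- function(tiers) {
  lev <- c("strong_hit", "weak_hit", "orphan_long_orf", "dark_matter")
  if (!length(tiers))
    return(data.frame(tier = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  counts <- table(factor(tiers, levels = lev))
  data.frame(tier = lev, count = as.integer(counts),
             fraction = as.numeric(counts) / length(tiers),
             stringsAsFactors = FALSE)
}

#' Gate a candidate on catalytic-motif evidence
#'
#' A candidate is `confirmed` only when motifs A, B and a canonical motif
#' C (GDD/SDD/GDN) are all located in order; anything less — including a
#' noncanonical C such as GFD — leaves it `unresolved`. Unresolved
#' candidates are retained and flagged, not discarded.
#'
#' @param annotation A motif annotation from [scan_motifs()].
#' @return `"confirmed"` or `"unresolved"`.
#' @export
motif_gate <- function(annotation) {
  ok <- !is.null(annotation$motifA) && !is.null(annotation$motifB) &&
    !is.null(annotation$motifC) && isTRUE(annotation$motifC_canonical)
  if (ok) "confirmed" else "unresolved"
}
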