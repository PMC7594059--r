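# Karlin-Altschul parameters for gapped BLOSUM62 with gap open 11 /
# extend 1 (the BLASTP defaults this search layer stands in for).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local protein alignment with Karlin-Altschul statistics
#'
#' Smith-Waterman optimal local alignment under BLOSUM62 with affine gap
#' penalties (open 11, extend 1), with bit score
#' `(lambda * S - ln K) / ln 2` and e-value `K * m * n * exp(-lambda * S)`
#' over a caller-supplied search space.
#'
#' @param query,target Amino-acid strings (nonempty).
#' @param gap_open,gap_extend Positive gap penalties; total cost of a gap
#'   of length g is `gap_open + g * gap_extend`.
#' @param search_space Product m*n used for the e-value; defaults to the
#'   two sequence lengths, but a reference-set search should pass query
#'   length times total reference residues.
#' @param query_id,target_id,target_label Labels carried into the hit.
#' @return One-row data.frame: `query_id`, `target_id`, `raw_score`,
#'   `bit_score`, `e_value`, `q_start`, `q_end`, `t_start`, `t_end`
#'   (0-based half-open), `target_label`.
#' @export
local_align <- function(query, target, gap_open = 11, gap_extend = 1,
                        search_space = NULL, query_id = "query",
                        target_id = "target", target_label = "nonviral") {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend, type = "local")
  S <- Biostrings::score(al)
  pr <- as.data.frame(Biostrings::pattern(al)@range)
  sr <- as.data.frame(Biostrings::subject(al)@range)
  if (is.null(search_space)) search_space <- nchar(query) * nchar(target)
  data.frame(
    query_id = query_id, target_id = target_id,
    raw_score = S,
    bit_score = (KA_LAMBDA * S - log(KA_K)) / log(2),
    e_value = KA_K * search_space * exp(-KA_LAMBDA * S),
    q_start = pr$start - 1L, q_end = pr$end,
    t_start = sr$start - 1L, t_end = sr$end,
    target_label = target_label,
    stringsAsFactors = FALSE
  )
}

#' Search query proteins against a labelled reference set
#'
#' Aligns every query against every reference protein and returns all
#' hits, e-values computed over the whole reference search space
#' (query length x total reference residues).
#'
#' @param queries Named character vector of amino-acid sequences, or a
#'   data.frame with `id` and `seq`.
#' @param reference data.frame with `id`, `seq` and `label`
#'   (`"viral"`/`"nonviral"`).
#' @param e_max Keep hits with e-value below this bound (default 10).
#' @return data.frame of hits sorted by bit score descending, tie-broken
#'   by target id.
#' @export
search_reference <- function(queries, reference, e_max = 10) {
  if (is.data.frame(queries)) queries <- stats::setNames(queries$seq, queries$id)
  empty <- data.frame(query_id = character(), target_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      e_value = numeric(), q_start = integer(),
                      q_end = integer(), t_start = integer(),
                      t_end = integer(), target_label = character(),
                      stringsAsFactors = FALSE)
  if (!length(queries) || !nrow(reference)) return(empty)
  total_ref <- sum(nchar(reference$seq))
  qset <- Biostrings::AAStringSet(queries)
  hits <- list()
  for (ti in seq_len(nrow(reference))) {
    al <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(reference$seq[ti]),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "local")
    S <- Biostrings::score(al)
    pr <- as.data.frame(Biostrings::pattern(al)@range)
    sr <- as.data.frame(Biostrings::subject(al)@range)
    hits[[ti]] <- data.frame(
      query_id = names(queries), target_id = reference$id[ti],
      raw_score = S,
      bit_score = (KA_LAMBDA * S - log(KA_K)) / log(2),
      e_value = KA_K * nchar(queries) * total_ref * exp(-KA_LAMBDA * S),
      q_start = pr$start - 1L, q_end = pr$end,
      t_start = sr$start - 1L, t_end = sr$end,
      target_label = reference$label[ti],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  out <- out[out$e_value <= e_max, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(-out$bit_score, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan ORFs against a set of profiles
#'
#' Scores every (ORF, profile) pair with local profile Viterbi. E-values
#' come from the profile's Gumbel calibration when present (multiplied by
#' the number of ORFs scanned); uncalibrated profiles yield `NA` unless
#' `shuffle_null = TRUE`, in which case a seeded permutation null
#' (`n_shuffle` residue shuffles of the query) is used.
#'
#' @param orfs ORF data.frame from [find_orfs()] (needs `orf_id`,
#'   `aa_seq`), or a named character vector of protein sequences.
#' @param profiles List of [profile_hmm] objects.
#' @param shuffle_null Use the permutation null for uncalibrated profiles.
#' @param n_shuffle Shuffles for the permutation null (default 200).
#' @param seed Seed for the permutation null.
#' @return data.frame of hits: `orf_id`, `profile_name`, `profile_class`,
#'   `bit_score`, `e_value`, `q_start`, `q_end`, sorted by bit score
#'   descending then profile name.
#' @export
scan_orfs <- function(orfs, profiles, shuffle_null = FALSE,
                      n_shuffle = 200, seed = 1) {
  if (is.data.frame(orfs)) {
    seqs <- stats::setNames(orfs$aa_seq, orfs$orf_id)
  } else seqs <- orfs
  empty <- data.frame(orf_id = character(), profile_name = character(),
                      profile_class = character(), bit_score = numeric(),
                      e_value = numeric(), q_start = integer(),
                      q_end = integer(), stringsAsFactors = FALSE)
  if (!length(seqs) || !length(profiles)) return(empty)
  n_targets <- length(seqs)
  rows <- vector("list", length(seqs) * length(profiles))
  r <- 0L
  for (si in seq_along(seqs)) {
    for (p in profiles) {
      v <- viterbi_score(p, seqs[[si]])
      if (!is.null(p$calibration)) {
        ev <- n_targets * profile_pvalue(p, v$score)
      } else if (shuffle_null) {
        ev <- n_targets * shuffle_pvalue(p, seqs[[si]], v$score,
                                         n = n_shuffle, seed = seed)
      } else ev <- NA_real_
      r <- r + 1L
      rows[[r]] <- data.frame(
        orf_id = names(seqs)[si], profile_name = p$name,
        profile_class = profile_class_of(p),
        bit_score = v$score, e_value = ev,
        q_start = v$q_start, q_end = v$q_end,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$bit_score, out$profile_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan an ORF for RdRp catalytic motifs A, B and C
#'
#' Motif C is the catalytic tripeptide, canonically GDD (SDD and GDN also
#' canonical): pattern `[GS]D[DN]`, with a noncanonical fallback
#' `[GS].[DN]` (capturing variants such as GFD). Motif A is an aspartate
#' pair `D-x(2,4)-D` and motif B a glycine-rich stretch followed by a
#' conserved N/T (`G-x(1,3)-[NT]`), both required upstream of C within
#' `window` residues, in the order A < B < C.
#'
#' @param aa_seq ORF amino-acid sequence.
#' @param window Span upstream of motif C within which A and B must lie
#'   (default 150 residues).
#' @return List: `motifA`, `motifB`, `motifC` (each `NULL` or
#'   `list(start, end, match)` with 0-based half-open positions),
#'   `motifC_canonical`, `motifC_variant`.
#' @export
scan_motifs <- function(aa_seq, window = 150) {
  find_all <- function(pattern, s, from = 1L, to = nchar(s)) {
    sub <- substr(s, from, to)
    m <- gregexpr(pattern, sub, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m) + from - 2L,  # 0-based
               len = attr(m, "match.length"))
  }
  ann <- list(motifA = NULL, motifB = NULL, motifC = NULL,
              motifC_canonical = FALSE, motifC_variant = NA_character_)
  n <- nchar(aa_seq)
  cand_c <- find_all("[GS]D[DN]", aa_seq)
  canonical <- TRUE
  if (is.null(cand_c)) {
    cand_c <- find_all("[GS][^GSDN*][DN]", aa_seq)
    canonical <- FALSE
  }
  if (is.null(cand_c)) return(ann)
  pick <- NULL
  # prefer a C placement that completes the A < B < C architecture
  for (ci in seq_len(nrow(cand_c))) {
    c0 <- cand_c$start[ci]
    lo <- max(0L, c0 - window)
    b <- find_all("G.{1,3}[NT]", aa_seq, from = lo + 1L, to = c0)
    if (is.null(b)) next
    for (bi in rev(seq_len(nrow(b)))) {  # B nearest to C first
      b0 <- b$start[bi]
      if (b$start[bi] + b$len[bi] > c0) next
      a <- find_all("D.{2,4}D", aa_seq, from = lo + 1L, to = b0)
      if (is.null(a)) next
      a <- a[a$start + a$len <= b0, , drop = FALSE]
      if (!nrow(a)) next
      pick <- list(a = a[nrow(a), ], b = b[bi, ], c = cand_c[ci, ])
      break
    }
    if (!is.null(pick)) break
  }
  mk <- function(row) if (is.null(row)) NULL else
    list(start = row$start, end = row$start + row$len,
         match = substr(aa_seq, row$start + 1L, row$start + row$len))
  if (is.null(pick)) {
    crow <- cand_c[nrow(cand_c), ]  # rightmost C candidate, partial call
    ann$motifC <- mk(crow)
  } else {
    ann$motifA <- mk(pick$a)
    ann$motifB <- mk(pick$b)
    ann$motifC <- mk(pick$c)
  }
  ann$motifC_variant <- ann$motifC$match
  ann$motifC_canonical <- canonical &&
    ann$motifC$match %in% c("GDD", "SDD", "GDN")
  ann
}
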