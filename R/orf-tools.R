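#' Six-frame ORF prediction as stop-free regions
#'
#' An ORF here is a maximal region free of stop codons in one of the six
#' reading frames, following the permissive convention used for viral
#' dark-matter screening: no start codon is required, and regions running
#' into a contig end are retained and flagged as partial. Trailing
#' incomplete codons are dropped. Codons containing N translate to `X`
#' and never terminate a region.
#'
#' @param contig A list or one-row data.frame with `id` and `seq`, or a
#'   plain nucleotide string (then `id` defaults to `"contig"`).
#' @param code Genetic code id: 1 (standard) or 4 (protozoan mitochondrial).
#' @param min_aa Minimum ORF length in amino acids (default 200, the gate
#'   used for orphan-contig screening: shorter than most RdRps but long
#'   enough for evolutionary inference).
#' @return data.frame with one row per ORF: `contig_id`, `strand` (+/-),
#'   `frame` (0/1/2, offset in reading direction), `start`, `end` (0-based
#'   half-open on the forward strand), `aa_seq`, `genetic_code`,
#'   `partial5`, `partial3` (relative to reading direction), `orf_id`.
#' @export
find_orfs <- function(contig, code = 1, min_aa = 200) {
  code <- normalize_code_id(code)
  if (is.character(contig)) contig <- list(id = "contig", seq = contig)
  id <- as.character(contig$id)
  seq <- toupper(as.character(contig$seq))
  L <- nchar(seq)
  if (L < 3L) stop("contig length must be >= 3")
  rc <- revcomp(seq)
  out <- list()
  for (strand in c("+", "-")) {
    work <- if (strand == "+") seq else rc
    for (frame in 0:2) {
      if (L - frame < 3L) next
      aa <- translate_dna(substr(work, frame + 1L, L), code)
      n_cod <- nchar(aa)
      if (n_cod == 0L) next
      is_stop <- strsplit(aa, "")[[1]] == "*"
      # maximal stop-free runs of codons
      r <- rle(is_stop)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (r$values[k]) next
        i <- starts[k] - 1L  # 0-based codon index of region start
        j <- ends[k]         # 0-based exclusive
        if (j - i < min_aa) next
        aa_seq <- substr(aa, i + 1L, j)
        # nt coords in reading direction
        rs <- frame + 3L * i
        re <- frame + 3L * j
        if (strand == "+") {
          start <- rs; end <- re
        } else {
          start <- L - re; end <- L - rs
        }
        out[[length(out) + 1L]] <- data.frame(
          contig_id = id, strand = strand, frame = frame,
          start = start, end = end, aa_seq = aa_seq,
          genetic_code = code,
          partial5 = (i == 0L),
          partial3 = (j == n_cod),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(contig_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      aa_seq = character(), genetic_code = integer(),
                      partial5 = logical(), partial3 = logical(),
                      orf_id = character(), stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$strand, res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res$orf_id <- sprintf("%s|%s|%d-%d|c%d", res$contig_id, res$strand,
                        res$start, res$end, res$genetic_code)
  res
}

#' Locate -1 ribosomal frameshift slippery sites
#'
#' Finds every occurrence of the slippery heptamer GGAUUUU (DNA form
#' GGATTTT) on either strand of a contig. At such sites ribosomes can slip
#' one nucleotide backwards, fusing two overlapping ORFs into a single
#' replicase.
#'
#' @param contig As in [find_orfs()].
#' @return data.frame with `pos` (0-based forward-strand start of the
#'   heptamer) and `strand`.
#' @export
detect_slippery_sites <- function(contig) {
  if (is.character(contig)) contig <- list(id = "contig", seq = contig)
  seq <- toupper(as.character(contig$seq))
  L <- nchar(seq)
  hepta <- "GGATTTT"
  fwd <- as.integer(gregexpr(hepta, seq, fixed = TRUE)[[1]])
  fwd <- fwd[fwd > 0L] - 1L
  rcv <- as.integer(gregexpr(hepta, revcomp(seq), fixed = TRUE)[[1]])
  rcv <- rcv[rcv > 0L] - 1L
  rev_pos <- L - (rcv + 7L)
  df <- rbind(
    if (length(fwd)) data.frame(pos = fwd, strand = "+", stringsAsFactors = FALSE),
    if (length(rev_pos)) data.frame(pos = rev_pos, strand = "-", stringsAsFactors = FALSE)
  )
  if (is.null(df)) df <- data.frame(pos = integer(), strand = character(),
                                    stringsAsFactors = FALSE)
  df[order(df$pos), , drop = FALSE]
}

#' Fuse two overlapping ORFs across a -1 frameshift
#'
#' Models translation through a slippery heptamer: ORF1 is translated up to
#' the last ORF1 codon boundary at or before the end of the heptamer, then
#' the ribosome resumes one nucleotide back, in the -1 frame, inside ORF2.
#' The fused protein is the ORF1 prefix followed by the ORF2 suffix.
#'
#' @param orf1,orf2 One-row ORF records (as returned by [find_orfs()]) on
#'   the same strand, with ORF2 in the -1 frame relative to ORF1.
#' @param slip_pos 0-based forward-strand start of the GGATTTT heptamer;
#'   the heptamer must lie inside the ORF1/ORF2 overlap.
#' @return List with `contig_id`, `slip_pos`, `orf1_id`, `orf2_id`,
#'   `fused_aa`, `motif`.
#' @export
join_frameshift_orfs <- function(orf1, orf2, slip_pos) {
  orf1 <- as.list(orf1); orf2 <- as.list(orf2)
  if (!identical(orf1$strand, orf2$strand))
    stop("frameshift ORFs must lie on the same strand")
  if (!identical(orf1$contig_id, orf2$contig_id))
    stop("frameshift ORFs must come from the same contig")
  strand <- orf1$strand
  # reading-direction coordinates (for '-' we mirror against an unknown
  # contig length; use coordinates relative to orf extents instead)
  if (strand == "+") {
    s1 <- orf1$start; e1 <- orf1$end
    s2 <- orf2$start; e2 <- orf2$end
    p <- slip_pos
  } else {
    # mirror: use negated coordinates so "downstream" is increasing
    s1 <- -orf1$end; e1 <- -orf1$start
    s2 <- -orf2$end; e2 <- -orf2$start
    p <- -(slip_pos + 7L)
  }
  if (((s2 - s1) %% 3L) != 2L)
    stop("ORF2 must be in the -1 frame relative to ORF1")
  ov_lo <- max(s1, s2); ov_hi <- min(e1, e2)
  if (p < ov_lo || (p + 7L) > ov_hi)
    stop("slippery heptamer must lie inside the ORF1/ORF2 overlap")
  b <- s1 + 3L * ((p + 7L - s1) %/% 3L)  # last orf1 codon boundary <= heptamer end
  resume <- b - 1L
  if (((resume - s2) %% 3L) != 0L || resume < s2 || resume >= e2)
    stop("resume point does not fall on an ORF2 codon boundary inside ORF2")
  n_prefix <- (b - s1) %/% 3L
  i_suffix <- (resume - s2) %/% 3L
  prefix <- substr(orf1$aa_seq, 1L, n_prefix)
  suffix <- substr(orf2$aa_seq, i_suffix + 1L, nchar(orf2$aa_seq))
  list(
    contig_id = orf1$contig_id,
    slip_pos = slip_pos,
    orf1_id = orf1$orf_id,
    orf2_id = orf2$orf_id,
    fused_aa = paste0(prefix, suffix),
    motif = "GGATTTT"
  )
}
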