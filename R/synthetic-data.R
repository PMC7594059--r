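# Stop-containing spacer blocks used to delimit planted ORFs. LEFT ends
# with TAA (stops the planted frame immediately upstream); RIGHT starts
# with TAA (stops it immediately downstream). Both contain stops in all
# three forward frames and use only TAA, which is a stop under both
# genetic codes 1 and 4.
LEFT_BLOCK <- "TTAATTAATTAA"
RIGHT_BLOCK <- "TAATTAATTAA"

sub_seed <- function(seed, k) (as.integer(seed) * 1009L + k) %% 2147483562L

random_protein <- function(n) {
  paste0(sample(AA_ALPHABET, n, replace = TRUE, prob = amino_background()),
         collapse = "")
}

#' Deterministic synthetic RdRp exemplar proteins
#'
#' Generates a ~470-residue synthetic RNA-dependent RNA polymerase-like
#' protein: background-composition sequence with the catalytic palm
#' motifs planted in order (motif A `DYSKD` near position 300, motif B
#' `GAMN` near 355, motif C `SGDD` near 395). These serve as profile
#' seeds and reference proteins; they are synthetic stand-ins, not
#' database sequences.
#'
#' @param i Exemplar index (any positive integer).
#' @param length Protein length (default 470).
#' @return Amino-acid string.
#' @export
rdrp_exemplar <- function(i = 1, length = 470) {
  with_local_seed(sub_seed(97L, i), {
    p <- strsplit(random_protein(length), "")[[1]]
    plant <- function(p, at, s) {
      substr_chars <- strsplit(s, "")[[1]]
      p[at:(at + base::length(substr_chars) - 1L)] <- substr_chars
      p
    }
    p <- plant(p, 300L, "DYSKD")
    p <- plant(p, 355L, "GAMN")
    p <- plant(p, 395L, "SGDD")
    paste0(p, collapse = "")
  })
}

# 1-based positions of the planted catalytic motifs in rdrp_exemplar()
# output; protected from mutation so homologs keep a functional palm.
rdrp_exemplar_motifs <- function() c(300:304, 355:358, 395:398)

#' Mutate a protein to a target percent identity
#'
#' Substitution-only divergence: `round(L * (1 - target/100))` positions
#' are chosen uniformly and replaced by a different residue drawn from a
#' BLOSUM62-derived exchangeability distribution. No indels, so realized
#' identity equals the planned number of unchanged positions (within
#' rounding of the target).
#'
#' @param protein Amino-acid string, length >= 20.
#' @param target_identity Percent identity in (0, 100].
#' @param seed Integer seed.
#' @param protect Optional 1-based positions never mutated (e.g. the
#'   catalytic motif residues, which real homologs conserve); must leave
#'   enough free positions to reach the target.
#' @return Mutated protein of the same length.
#' @export
mutate_protein <- function(protein, target_identity, seed, protect = integer()) {
  if (target_identity <= 0 || target_identity > 100)
    stop("target_identity must be in (0, 100]")
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  if (L < 20) stop("protein length must be >= 20")
  n_mut <- round(L * (1 - target_identity / 100))
  if (n_mut == 0) return(protein)
  free <- setdiff(seq_len(L), protect)
  if (length(free) < n_mut)
    stop("too few unprotected positions to reach the target identity")
  bg <- amino_background()
  b62 <- blosum62_matrix()[AA_ALPHABET, AA_ALPHABET]
  with_local_seed(seed, {
    pos <- sample(free, n_mut)
    for (p in pos) {
      orig <- chars[p]
      if (!orig %in% AA_ALPHABET) next
      w <- bg * 2^(b62[, orig] / 2)
      w[orig] <- 0  # must substitute
      chars[p] <- sample(AA_ALPHABET, 1, prob = w)
    }
  })
  paste0(chars, collapse = "")
}

# Uniform random synonymous back-translation under a genetic code.
back_translate <- function(aa, code = 1) {
  tab <- genetic_code_table(code)
  by_aa <- split(names(tab), tab)
  chars <- strsplit(aa, "")[[1]]
  codons <- vapply(chars, function(a) {
    cands <- by_aa[[a]]
    if (is.null(cands)) stop("cannot back-translate residue '", a, "'")
    if (length(cands) == 1) cands else sample(cands, 1)
  }, character(1))
  paste0(codons, collapse = "")
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random codon string with a stop-frequency knob: each codon is a stop
# with probability stop_freq, else a uniform sense codon. Controls how
# often host contigs carry ORFs >= 200 aa.
random_codon_dna <- function(n_codons, stop_freq = 0.02, code = 1) {
  tab <- genetic_code_table(code)
  stops <- names(tab)[tab == "*"]
  sense <- names(tab)[tab != "*"]
  is_stop <- stats::runif(n_codons) < stop_freq
  codons <- character(n_codons)
  codons[is_stop] <- sample(stops, sum(is_stop), replace = TRUE)
  codons[!is_stop] <- sample(sense, sum(!is_stop), replace = TRUE)
  paste0(codons, collapse = "")
}

#' Specify a planted virus
#'
#' @param name Virus label.
#' @param rdrp_source Seed RdRp protein: an amino-acid string, or an
#'   integer index into [rdrp_exemplar()].
#' @param target_identity Percent amino-acid identity of the planted RdRp
#'   to its source, in (0, 100].
#' @param genome_architecture One of `single_orf`, `two_orf_frameshift`,
#'   `two_orf_adjacent`.
#' @param genetic_code `"standard"` (1) or `"protozoan_mitochondrial"` (4).
#' @param genome_length Contig length in nt (padded with UTRs; must
#'   accommodate the encoded ORFs).
#' @param read_count Planted read count for the contig.
#' @param in_reference Whether the source RdRp is part of the labelled
#'   reference set (`TRUE`: the virus is detectable by the similarity
#'   route; `FALSE`: a novel clade only reachable through the profile
#'   screen of orphan contigs).
#' @return List of class `virus_plan`.
#' @export
virus_plan <- function(name, rdrp_source = 1, target_identity = 40,
                       genome_architecture = c("single_orf",
                                               "two_orf_frameshift",
                                               "two_orf_adjacent"),
                       genetic_code = "standard",
                       genome_length = 2400, read_count = 500,
                       in_reference = TRUE) {
  genome_architecture <- match.arg(genome_architecture)
  if (target_identity <= 0 || target_identity > 100)
    stop("target_identity must be in (0, 100]")
  structure(list(
    name = name, rdrp_source = rdrp_source,
    target_identity = target_identity,
    genome_architecture = genome_architecture,
    genetic_code = normalize_code_id(genetic_code),
    genome_length = genome_length, read_count = read_count,
    in_reference = in_reference
  ), class = "virus_plan")
}

resolve_rdrp_source <- function(src) {
  if (is.character(src) && nchar(src) > 30) return(src)
  rdrp_exemplar(as.integer(src))
}

#' Plant a viral contig from a virus plan
#'
#' Builds a nucleotide contig realising the plan: the source RdRp is
#' mutated to the target identity, back-translated under the plan's
#' genetic code, and embedded between stop blocks. `two_orf_frameshift`
#' genomes place a 5' hypothetical-protein ORF whose overlap with the -1
#' frame RdRp ORF contains the GGATTTT slippery heptamer;
#' `two_orf_adjacent` genomes place the two ORFs in tandem.
#'
#' @param plan A [virus_plan()].
#' @param seed Integer seed.
#' @param contig_id Contig id (default derived from the virus name).
#' @return List with `contig` (list `id`, `seq`) and `truth` (one-row
#'   data.frame: coordinates of the RdRp ORF, slip position, planted
#'   identity, the planted RdRp/replicase protein, ...).
#' @export
plant_viral_contig <- function(plan, seed, contig_id = NULL) {
  stopifnot(inherits(plan, "virus_plan"))
  if (is.null(contig_id)) contig_id <- paste0("tig_", plan$name)
  source_aa <- resolve_rdrp_source(plan$rdrp_source)
  protect <- if (is.character(plan$rdrp_source) &&
                 nchar(plan$rdrp_source) > 30) integer()
    else rdrp_exemplar_motifs()
  mutated <- mutate_protein(source_aa, plan$target_identity,
                            sub_seed(seed, 1L), protect = protect)
  code <- plan$genetic_code
  with_local_seed(sub_seed(seed, 2L), {
    if (plan$genome_architecture == "single_orf") {
      bt <- back_translate(mutated, code)
      core <- paste0(LEFT_BLOCK, bt, RIGHT_BLOCK)
      pad <- plan$genome_length - nchar(core)
      if (pad < 0)
        stop("genome_length ", plan$genome_length,
             " cannot accommodate a ", nchar(core), " nt core")
      utr5 <- random_dna(pad %/% 2)
      utr3 <- random_dna(pad - nchar(utr5))
      seq <- paste0(utr5, core, utr3)
      orf_start <- nchar(utr5) + nchar(LEFT_BLOCK)
      orf_end <- orf_start + nchar(bt)
      slip <- NA_integer_
      planted_aa <- mutated
    } else if (plan$genome_architecture == "two_orf_adjacent") {
      p1 <- random_protein(150)
      bt1 <- back_translate(p1, code)
      bt2 <- back_translate(mutated, code)
      mid <- "TAATTAATTAATTAA"  # starts and ends with TAA
      core <- paste0(LEFT_BLOCK, bt1, mid, bt2, RIGHT_BLOCK)
      pad <- plan$genome_length - nchar(core)
      if (pad < 0)
        stop("genome_length ", plan$genome_length,
             " cannot accommodate a ", nchar(core), " nt core")
      utr5 <- random_dna(pad %/% 2)
      utr3 <- random_dna(pad - nchar(utr5))
      seq <- paste0(utr5, core, utr3)
      orf_start <- nchar(utr5) + nchar(LEFT_BLOCK) + nchar(bt1) + nchar(mid)
      orf_end <- orf_start + nchar(bt2)
      slip <- NA_integer_
      planted_aa <- mutated
    } else {  # two_orf_frameshift
      a_len <- 120L  # 5' hypothetical-protein codons before the slip
      p1 <- random_protein(a_len)
      bt1 <- back_translate(p1, code)
      # ORF2 after the -1 slip: resume codon is TT+x; force x = T (Phe),
      # then the rest of the mutated RdRp from residue 2 on
      p2_tail <- substr(mutated, 2, nchar(mutated))
      bt2 <- back_translate(p2_tail, code)
      core <- paste0(LEFT_BLOCK, bt1, "GGATTTT", "T", bt2, RIGHT_BLOCK)
      pad <- plan$genome_length - nchar(core)
      if (pad < 0)
        stop("genome_length ", plan$genome_length,
             " cannot accommodate a ", nchar(core), " nt core")
      utr5 <- random_dna(pad %/% 2)
      utr3 <- random_dna(pad - nchar(utr5))
      seq <- paste0(utr5, core, utr3)
      s1 <- nchar(utr5) + nchar(LEFT_BLOCK)       # ORF1 frame boundary
      slip <- s1 + 3L * a_len                     # heptamer start
      orf_start <- slip + 5L                      # first -1 frame codon
      orf_end <- orf_start + 3L * (1L + nchar(p2_tail))
      # fused replicase implied by the slip rule: ORF1 prefix through the
      # heptamer (G, F), then F from the re-read TTT, then the RdRp tail
      planted_aa <- paste0(p1, "GF", "F", p2_tail)
    }
    truth <- data.frame(
      contig_id = contig_id, class = "virus", virus_name = plan$name,
      orf_start = orf_start, orf_end = orf_end, strand = "+",
      slip_pos = slip, architecture = plan$genome_architecture,
      genetic_code = code, planted_identity = plan$target_identity,
      read_count = plan$read_count, rdrp_aa = planted_aa,
      stringsAsFactors = FALSE
    )
    list(contig = list(id = contig_id, seq = seq), truth = truth)
  })
}

#' Specify a synthetic metatranscriptome library
#'
#' The plan fixes the composition of a mock nonaxenic algal culture
#' library: abundant host-like contigs (a fraction of which are derived
#' from reference host proteins and therefore yield strong similarity
#' hits), rRNA-like repeat contigs, bacteriophage decoy contigs whose
#' ORFs resemble the decoy profiles, and planted divergent RNA viruses.
#'
#' @param n_host_contigs Number of host-like contigs (default 30).
#' @param host_length_range Host contig length range in nt
#'   (default c(450, 2400)).
#' @param n_decoy_phage Number of phage decoy contigs (default 4).
#' @param planted_viruses List of [virus_plan()]s.
#' @param abundance_lognormal_params `c(meanlog, sdlog)` of the log-normal
#'   read-count weights (default c(4, 1.5)).
#' @param total_non_rrna_reads Library total of non-rRNA reads
#'   (default 2e6).
#' @param seed Integer seed; the same plan and seed give byte-identical
#'   output.
#' @param n_rrna_like Number of rRNA-like repeat contigs (default 6).
#' @param host_stop_freq Stop-codon frequency in random host codon
#'   strings (default 0.012; low enough that a fair fraction of hosts
#'   carry ORFs >= 200 aa and populate the orphan tier).
#' @param host_ref_fraction Fraction of host contigs derived from
#'   reference host proteins (default 0.5).
#' @return List of class `library_plan`.
#' @export
library_plan <- function(n_host_contigs = 30,
                         host_length_range = c(450, 2400),
                         n_decoy_phage = 4,
                         planted_viruses = list(),
                         abundance_lognormal_params = c(4, 1.5),
                         total_non_rrna_reads = 2e6,
                         seed = 1,
                         n_rrna_like = 6,
                         host_stop_freq = 0.012,
                         host_ref_fraction = 0.5) {
  stopifnot(n_host_contigs >= 0, n_decoy_phage >= 0, n_rrna_like >= 0,
            total_non_rrna_reads >= 0)
  vsum <- sum(vapply(planted_viruses, function(v) v$read_count, numeric(1)))
  if (total_non_rrna_reads < vsum)
    stop("total_non_rrna_reads must be >= the sum of planted virus read counts")
  structure(list(
    n_host_contigs = n_host_contigs,
    host_length_range = host_length_range,
    n_decoy_phage = n_decoy_phage,
    planted_viruses = planted_viruses,
    abundance_lognormal_params = abundance_lognormal_params,
    total_non_rrna_reads = total_non_rrna_reads,
    seed = as.integer(seed),
    n_rrna_like = n_rrna_like,
    host_stop_freq = host_stop_freq,
    host_ref_fraction = host_ref_fraction
  ), class = "library_plan")
}

#' Default study-condition library plan
#'
#' Three planted divergent viruses spanning the architectures and the
#' abundance classes: a very divergent single-ORF virus, a -1 frameshift
#' virus translated with the protozoan mitochondrial code at very high
#' abundance, and a two-ORF virus at average abundance.
#'
#' @param seed Integer seed.
#' @return A [library_plan()].
#' @export
default_library_plan <- function(seed = 1) {
  library_plan(
    planted_viruses = list(
      virus_plan("algavirus_a", rdrp_source = 1, target_identity = 80,
                 genome_architecture = "single_orf",
                 genome_length = 2400, read_count = 1000),
      virus_plan("algavirus_b", rdrp_source = 2, target_identity = 60,
                 genome_architecture = "two_orf_frameshift",
                 genetic_code = "protozoan_mitochondrial",
                 genome_length = 2600, read_count = 25000),
      virus_plan("algavirus_c", rdrp_source = 3, target_identity = 40,
                 genome_architecture = "two_orf_adjacent",
                 genome_length = 2600, read_count = 200,
                 in_reference = FALSE)
    ),
    seed = seed
  )
}

.profile_cache <- new.env(parent = emptyenv())

# Build-and-calibrate a profile once per (source, name, class); the
# Gumbel null depends only on the profile, so a fixed calibration seed
# keeps output deterministic and identical across libraries.
cached_profile <- function(source_aa, name, class, calib_seed = 20231L) {
  key <- paste(name, class, nchar(source_aa),
               substr(source_aa, 1, 25), sep = "|")
  hit <- get0(key, envir = .profile_cache)
  if (!is.null(hit)) return(hit)
  p <- profile_from_protein(source_aa, name, class = class)
  p <- calibrate_profile(p, seed = calib_seed)
  assign(key, p, envir = .profile_cache)
  p
}

host_reference_proteins <- function(n = 10) {
  with_local_seed(3301L, {
    stats::setNames(
      vapply(seq_len(n), function(i) random_protein(320), character(1)),
      sprintf("host_ref_%02d", seq_len(n)))
  })
}

phage_decoy_proteins <- function(n = 4) {
  with_local_seed(2201L, {
    stats::setNames(
      vapply(seq_len(n), function(i) random_protein(350), character(1)),
      sprintf("phage_decoy_%02d", seq_len(n)))
  })
}

#' Generate a synthetic metatranscriptome library
#'
#' Deterministically realises a [library_plan()]: contigs, per-contig
#' read counts, a truth table, a labelled protein reference set (viral
#' RdRp sources plus nonviral host proteins) and calibrated profiles
#' (one RdRp profile per distinct virus source, plus phage decoy
#' profiles). When `out_dir` is given, writes `contigs.fasta`,
#' `counts.tsv`, `truth.tsv`, `reference.fasta` and `profiles.hmm`.
#'
#' @param plan A [library_plan()].
#' @param out_dir Optional output directory (created if needed).
#' @param library Library tag (default "synthlib").
#' @return List: `contigs`, `counts`, `truth` (data.frames), `reference`,
#'   `profiles`, `plan`, and `files` when written.
#' @export
generate_library <- function(plan, out_dir = NULL, library = "synthlib") {
  stopifnot(inherits(plan, "library_plan"))
  host_refs <- host_reference_proteins()
  phage_refs <- phage_decoy_proteins(max(plan$n_decoy_phage, 1))
  contigs <- list(); truth <- list()
  with_local_seed(sub_seed(plan$seed, 11L), {
    # host-like contigs
    n_ref_host <- round(plan$n_host_contigs * plan$host_ref_fraction)
    for (i in seq_len(plan$n_host_contigs)) {
      id <- sprintf("%s_h%03d", library, i)
      if (i <= n_ref_host) {
        src <- host_refs[[1 + (i - 1) %% length(host_refs)]]
        aa <- mutate_protein(src, 85, sub_seed(plan$seed, 100L + i))
        bt <- back_translate(aa, 1)
        seq <- paste0(random_dna(30), LEFT_BLOCK, bt, RIGHT_BLOCK,
                      random_dna(30))
      } else {
        len <- sample(seq(plan$host_length_range[1],
                          plan$host_length_range[2]), 1)
        seq <- random_codon_dna(len %/% 3, plan$host_stop_freq)
      }
      contigs[[id]] <- seq
      truth[[id]] <- data.frame(
        contig_id = id, class = "host", virus_name = NA_character_,
        orf_start = NA_integer_, orf_end = NA_integer_,
        strand = NA_character_, slip_pos = NA_integer_,
        architecture = NA_character_, genetic_code = NA_integer_,
        planted_identity = NA_real_, read_count = NA_real_,
        rdrp_aa = NA_character_, stringsAsFactors = FALSE)
    }
    # rRNA-like repeat contigs
    for (i in seq_len(plan$n_rrna_like)) {
      id <- sprintf("%s_r%03d", library, i)
      unit <- random_dna(60)
      contigs[[id]] <- paste0(strrep(unit, 12))
      truth[[id]] <- data.frame(
        contig_id = id, class = "rrna_like", virus_name = NA_character_,
        orf_start = NA_integer_, orf_end = NA_integer_,
        strand = NA_character_, slip_pos = NA_integer_,
        architecture = NA_character_, genetic_code = NA_integer_,
        planted_identity = NA_real_, read_count = NA_real_,
        rdrp_aa = NA_character_, stringsAsFactors = FALSE)
    }
    # phage decoy contigs: orphan ORFs similar to the decoy profiles
    for (i in seq_len(plan$n_decoy_phage)) {
      id <- sprintf("%s_p%03d", library, i)
      src <- phage_refs[[1 + (i - 1) %% length(phage_refs)]]
      aa <- mutate_protein(src, 70, sub_seed(plan$seed, 200L + i))
      bt <- back_translate(aa, 1)
      contigs[[id]] <- paste0(random_dna(25), LEFT_BLOCK, bt, RIGHT_BLOCK,
                              random_dna(25))
      truth[[id]] <- data.frame(
        contig_id = id, class = "phage_decoy", virus_name = NA_character_,
        orf_start = NA_integer_, orf_end = NA_integer_,
        strand = NA_character_, slip_pos = NA_integer_,
        architecture = NA_character_, genetic_code = NA_integer_,
        planted_identity = NA_real_, read_count = NA_real_,
        rdrp_aa = NA_character_, stringsAsFactors = FALSE)
    }
  })
  # planted viruses
  for (vi in seq_along(plan$planted_viruses)) {
    vp <- plan$planted_viruses[[vi]]
    pv <- plant_viral_contig(vp, sub_seed(plan$seed, 300L + vi),
                             contig_id = sprintf("%s_v%03d", library, vi))
    contigs[[pv$contig$id]] <- pv$contig$seq
    truth[[pv$contig$id]] <- pv$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  # read counts: planted viruses keep their counts; the remaining
  # non-rRNA reads are spread over host and phage contigs with
  # log-normal weights; rRNA-like contigs get counts outside the total
  mlog <- plan$abundance_lognormal_params[1]
  slog <- plan$abundance_lognormal_params[2]
  with_local_seed(sub_seed(plan$seed, 12L), {
    is_virus <- truth$class == "virus"
    is_rrna <- truth$class == "rrna_like"
    vsum <- sum(truth$read_count[is_virus])
    remaining <- plan$total_non_rrna_reads - vsum
    n_other <- sum(!is_virus & !is_rrna)
    if (n_other > 0) {
      w <- stats::rlnorm(n_other, mlog, slog)
      truth$read_count[!is_virus & !is_rrna] <-
        floor(remaining * 0.95 * w / sum(w))
    }
    if (any(is_rrna))
      truth$read_count[is_rrna] <- round(stats::rlnorm(sum(is_rrna),
                                                       mlog + 4, slog))
    # shuffle contig order so class is not positional
    ord <- sample(nrow(truth))
  })
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  contig_df <- data.frame(
    id = truth$contig_id,
    seq = unname(unlist(contigs[truth$contig_id])),
    library = library,
    read_count = truth$read_count,
    stringsAsFactors = FALSE)
  counts <- data.frame(contig_id = truth$contig_id,
                       read_count = truth$read_count,
                       stringsAsFactors = FALSE)
  # reference set: unmutated viral RdRp sources (only those declared part
  # of the reference databases) + nonviral host proteins
  all_sources <- unique(vapply(plan$planted_viruses, function(v)
    resolve_rdrp_source(v$rdrp_source), character(1)))
  ref_flag <- vapply(all_sources, function(s) {
    any(vapply(plan$planted_viruses, function(v)
      identical(resolve_rdrp_source(v$rdrp_source), s) &&
        isTRUE(v$in_reference), logical(1)))
  }, logical(1))
  reference <- rbind(
    if (any(ref_flag))
      data.frame(id = sprintf("viral_rdrp_src_%02d", which(ref_flag)),
                 seq = all_sources[ref_flag], label = "viral",
                 stringsAsFactors = FALSE),
    data.frame(id = names(host_refs), seq = unname(host_refs),
               label = "nonviral", stringsAsFactors = FALSE))
  # profiles: one RdRp profile per viral source + phage decoys; profiles
  # and their null calibration are properties of the source protein, not
  # of the library, so the calibration seed is fixed and results cached
  profiles <- list()
  for (i in seq_along(all_sources)) {
    profiles[[length(profiles) + 1L]] <- cached_profile(
      all_sources[i], sprintf("rdrp_profile_%02d", i), "rdrp_viral")
  }
  for (i in seq_along(phage_refs)) {
    profiles[[length(profiles) + 1L]] <- cached_profile(
      phage_refs[[i]], paste0("decoy_", names(phage_refs)[i]), "decoy")
  }
  out <- list(contigs = contig_df, counts = counts, truth = truth,
              reference = reference, profiles = profiles, plan = plan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- list(
      contigs = file.path(out_dir, "contigs.fasta"),
      counts = file.path(out_dir, "counts.tsv"),
      truth = file.path(out_dir, "truth.tsv"),
      reference = file.path(out_dir, "reference.fasta"),
      profiles = file.path(out_dir, "profiles.hmm"))
    write_fasta(contig_df, f$contigs)
    write_tsv(counts, f$counts)
    write_tsv(truth, f$truth)
    write_fasta(stats::setNames(reference$seq,
                                paste(reference$id, reference$label)),
                f$reference)
    write_hmmer3_profile(profiles, f$profiles)
    out$files <- f
  }
  out
}

#' Read a labelled reference protein FASTA
#'
#' Headers carry the label as the second whitespace-separated token
#' (`>id viral` / `>id nonviral`); records without one default to
#' `nonviral`.
#'
#' @param path FASTA path.
#' @return data.frame with `id`, `seq`, `label`.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  label <- ifelse(grepl("\\sviral\\b", hdr), "viral", "nonviral")
  data.frame(id = id, seq = toupper(unname(as.character(ss))),
             label = label, stringsAsFactors = FALSE)
}
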