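#' Pipeline run configuration
#'
#' @param contigs Path to a contig FASTA, or a contig data.frame.
#' @param profiles Path to a HMMER3-dialect profile file, or a list of
#'   [profile_hmm] objects.
#' @param reference Path to a labelled reference FASTA (see
#'   [read_reference_fasta()]), or a data.frame with `id`, `seq`, `label`.
#' @param counts Optional counts TSV path or data.frame
#'   (`contig_id`, `read_count`).
#' @param total_non_rrna Library total of non-rRNA reads; default: sum of
#'   the supplied counts.
#' @param min_orf_aa Long-ORF gate (default 200).
#' @param e_strong,e_weak Similarity-tier e-value bounds
#'   (defaults 1e-05, 1e-03).
#' @param profile_e_max Profile-hit significance bound on the orphan
#'   route (default 1e-03).
#' @param demarcation_thresholds Percent-identity species thresholds to
#'   apply (default c(90, 50)).
#' @param genetic_codes Genetic codes tried for ORF prediction
#'   (default c(1, 4)).
#' @param min_search_aa Minimum ORF length used as similarity-search
#'   query (default 80).
#' @param seed Integer seed.
#' @param out_dir Output directory (default `tempfile()`).
#' @return List of class `run_config`.
#' @export
run_config <- function(contigs, profiles, reference, counts = NULL,
                       total_non_rrna = NULL, min_orf_aa = 200,
                       e_strong = 1e-5, e_weak = 1e-3,
                       profile_e_max = 1e-3,
                       demarcation_thresholds = c(90, 50),
                       genetic_codes = c(1, 4), min_search_aa = 80,
                       seed = 1, out_dir = tempfile("prospector_run_")) {
  if (e_strong >= e_weak) stop("e-value bounds must satisfy e_strong < e_weak")
  if (any(demarcation_thresholds <= 0 | demarcation_thresholds > 100))
    stop("demarcation thresholds must lie in (0, 100]")
  for (p in list(contigs, profiles, reference, counts)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("input not found: ", p)
  }
  structure(list(
    contigs = contigs, profiles = profiles, reference = reference,
    counts = counts, total_non_rrna = total_non_rrna,
    min_orf_aa = min_orf_aa, e_strong = e_strong, e_weak = e_weak,
    profile_e_max = profile_e_max,
    demarcation_thresholds = demarcation_thresholds,
    genetic_codes = vapply(genetic_codes, normalize_code_id, integer(1)),
    min_search_aa = min_search_aa,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

profile_consensus <- function(profile) {
  paste0(AA_ALPHABET[apply(profile$match_emissions, 1, which.max)],
         collapse = "")
}

load_run_inputs <- function(config) {
  contigs <- if (is.character(config$contigs))
    read_fasta(config$contigs) else config$contigs
  profiles <- if (is.character(config$profiles))
    parse_hmmer3_profile(config$profiles) else config$profiles
  reference <- if (is.character(config$reference))
    read_reference_fasta(config$reference) else config$reference
  if (!is.null(config$counts)) {
    if (is.character(config$counts)) {
      contigs <- attach_counts(contigs, config$counts)
    } else {
      idx <- match(contigs$id, config$counts$contig_id)
      contigs$read_count <- config$counts$read_count[idx]
    }
  }
  list(contigs = contigs, profiles = profiles, reference = reference)
}

#' Run the full virus-prospecting pipeline
#'
#' Orchestrates ORF prediction, reference similarity triage, profile-HMM
#' screening of orphan contigs with decoy arbitration, catalytic-motif
#' gating, abundance accounting and pairwise-identity demarcation, and
#' writes deterministic TSV/newick reports plus a run log to the
#' configured output directory.
#'
#' @param config A [run_config()].
#' @return Invisible list: `triage` (per-contig tiers and verdicts),
#'   `tier_summary`, `candidates` (report rows), `demarcation` (per
#'   threshold), `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_run_inputs(config)
  contigs <- inputs$contigs
  profiles <- inputs$profiles
  reference <- inputs$reference
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    "rdrprospector run",
    sprintf("seed: %d", config$seed),
    sprintf("contigs: %d", nrow(contigs)),
    sprintf("profiles: %d (%s)", length(profiles),
            paste(vapply(profiles, function(p) p$name, character(1)),
                  collapse = ", ")),
    sprintf("reference proteins: %d", nrow(reference)),
    sprintf("e-value bounds: strong < %g, weak < %g", config$e_strong,
            config$e_weak),
    sprintf("profile e-value bound: %g", config$profile_e_max),
    sprintf("long-ORF gate: %d aa", config$min_orf_aa),
    sprintf("genetic codes: %s", paste(config$genetic_codes, collapse = ",")),
    sprintf("demarcation thresholds: %s",
            paste(config$demarcation_thresholds, collapse = ",")))
  total <- config$total_non_rrna
  if (is.null(total)) {
    total <- if (all(is.na(contigs$read_count))) NA_real_
      else sum(contigs$read_count, na.rm = TRUE)
  }
  # phase 1: ORFs for every contig under every configured genetic code
  orfs_by_contig <- vector("list", nrow(contigs))
  for (ci in seq_len(nrow(contigs))) {
    ctg <- list(id = contigs$id[ci], seq = contigs$seq[ci])
    o <- do.call(rbind, lapply(config$genetic_codes, function(code)
      find_orfs(ctg, code = code, min_aa = config$min_search_aa)))
    orfs_by_contig[[ci]] <- o
  }
  # phase 2: one batched reference search over the longest frames of
  # every contig (stand-in for the BLASTx stage)
  qorf_list <- lapply(orfs_by_contig, function(orfs) {
    q <- orfs[order(-nchar(orfs$aa_seq)), , drop = FALSE]
    q <- q[!duplicated(paste(q$strand, q$frame)), , drop = FALSE]
    utils::head(q, 3L)
  })
  all_qorfs <- do.call(rbind, qorf_list)
  all_ref_hits <- if (!is.null(all_qorfs) && nrow(all_qorfs))
    search_reference(stats::setNames(all_qorfs$aa_seq, all_qorfs$orf_id),
                     reference)
  else search_reference(character(), reference)
  # phase 3: tiers, then one batched profile scan of orphan long ORFs
  tiers <- character(nrow(contigs))
  for (ci in seq_len(nrow(contigs))) {
    orfs <- orfs_by_contig[[ci]]
    long_orfs <- orfs[nchar(orfs$aa_seq) >= config$min_orf_aa, , drop = FALSE]
    ref_hits <- all_ref_hits[all_ref_hits$query_id %in% orfs$orf_id, ,
                             drop = FALSE]
    tiers[ci] <- classify_contig(contigs$id[ci], ref_hits, long_orfs,
                                 e_strong = config$e_strong,
                                 e_weak = config$e_weak,
                                 min_aa = config$min_orf_aa)
  }
  orphan_orfs <- do.call(rbind, lapply(which(tiers == "orphan_long_orf"),
    function(ci) {
      o <- orfs_by_contig[[ci]]
      o <- o[nchar(o$aa_seq) >= config$min_orf_aa, , drop = FALSE]
      o[!duplicated(o$aa_seq), , drop = FALSE]
    }))
  all_prof_hits <- if (!is.null(orphan_orfs) && nrow(orphan_orfs) &&
                       length(profiles)) {
    ph <- scan_orfs(orphan_orfs, profiles)
    ph[!is.na(ph$e_value) & ph$e_value <= config$profile_e_max, ,
       drop = FALSE]
  } else NULL
  # phase 4: per-contig arbitration and candidate reporting
  triage_rows <- list()
  candidates <- list()
  for (ci in seq_len(nrow(contigs))) {
    cid <- contigs$id[ci]
    ctg <- list(id = cid, seq = contigs$seq[ci])
    orfs <- orfs_by_contig[[ci]]
    long_orfs <- orfs[nchar(orfs$aa_seq) >= config$min_orf_aa, , drop = FALSE]
    tier <- tiers[ci]
    ref_hits <- all_ref_hits[all_ref_hits$query_id %in% orfs$orf_id, ,
                             drop = FALSE]
    prof_hits <- if (!is.null(all_prof_hits))
      all_prof_hits[all_prof_hits$orf_id %in% long_orfs$orf_id, ,
                    drop = FALSE]
    else NULL
    sig_ref <- ref_hits[ref_hits$e_value < config$e_weak, , drop = FALSE]
    verdict <- arbitrate_candidate(prof_hits, sig_ref)
    candidate <- verdict$candidate &&
      (tier %in% c("strong_hit", "weak_hit", "orphan_long_orf"))
    route <- if (!candidate) NA_character_
      else if (verdict$best_class %in% "viral") "similarity" else "profile"
    triage_rows[[ci]] <- data.frame(
      contig_id = cid, tier = tier,
      best_hit = verdict$best_name, best_class = verdict$best_class,
      best_score = verdict$best_score,
      candidate_virus = candidate,
      rejection_reason = if (candidate) NA_character_ else verdict$reason,
      stringsAsFactors = FALSE)
    if (candidate) {
      # candidate ORF: the ORF behind the winning hit
      if (route == "profile") {
        best_orf_id <- prof_hits$orf_id[1]
        cand_aa <- long_orfs$aa_seq[match(best_orf_id, long_orfs$orf_id)]
        best_prof <- profiles[[match(verdict$best_name,
                                     vapply(profiles, function(p) p$name,
                                            character(1)))]]
        pid <- global_identity(cand_aa, profile_consensus(best_prof))
      } else {
        best_orf_id <- sig_ref$query_id[1]
        cand_aa <- orfs$aa_seq[match(best_orf_id, orfs$orf_id)]
        tgt <- reference$seq[match(verdict$best_name, reference$id)]
        pid <- global_identity(cand_aa, tgt)
      }
      ann <- scan_motifs(cand_aa)
      slips <- detect_slippery_sites(ctg)
      code_used <- orfs$genetic_code[match(best_orf_id, orfs$orf_id)]
      rc <- contigs$read_count[ci]
      pct <- if (!is.na(rc) && !is.na(total) && total > 0)
        abundance(rc, total) else NA_real_
      candidates[[length(candidates) + 1L]] <- data.frame(
        candidate = paste0("candidate_", cid),
        contig_id = cid, length_nt = nchar(ctg$seq),
        read_count = rc, percent_non_rrna = pct,
        abundance_class = if (is.na(pct)) NA_character_
          else classify_abundance(pct),
        route = route, best_hit = verdict$best_name,
        best_class = verdict$best_class,
        bit_score = verdict$best_score,
        percent_identity = round(pid, 1),
        motif_confidence = motif_gate(ann),
        motif_c = if (is.null(ann$motifC)) NA_character_
          else ann$motifC_variant,
        n_slippery = nrow(slips),
        genetic_code = code_used,
        orf_id = best_orf_id, orf_aa = cand_aa,
        stringsAsFactors = FALSE)
    }
  }
  triage <- do.call(rbind, triage_rows)
  tier_summary <- summarize_tiers(triage$tier)
  cand_df <- if (length(candidates)) do.call(rbind, candidates) else
    data.frame(candidate = character(), contig_id = character(),
               length_nt = integer(), read_count = numeric(),
               percent_non_rrna = numeric(), abundance_class = character(),
               route = character(), best_hit = character(),
               best_class = character(), bit_score = numeric(),
               percent_identity = numeric(), motif_confidence = character(),
               motif_c = character(), n_slippery = integer(),
               genetic_code = integer(), orf_id = character(),
               orf_aa = character(), stringsAsFactors = FALSE)
  # demarcation across candidate RdRps
  demarcation <- list()
  if (nrow(cand_df) >= 2) {
    m <- identity_matrix(stats::setNames(cand_df$orf_aa, cand_df$candidate))
    for (thr in config$demarcation_thresholds) {
      cl <- cluster_species(m, thr)
      demarcation[[as.character(thr)]] <- cl
    }
    demarcation$matrix <- m
    if (nrow(m) >= 3) demarcation$newick <- nj_tree(m)
  }
  files <- list(
    triage = file.path(config$out_dir, "triage.tsv"),
    tiers = file.path(config$out_dir, "tier_summary.tsv"),
    candidates = file.path(config$out_dir, "candidates.tsv"),
    log = file.path(config$out_dir, "run.log"))
  write_tsv(triage, files$triage)
  write_tsv(tier_summary, files$tiers)
  write_tsv(cand_df[, setdiff(names(cand_df), "orf_aa")], files$candidates)
  write_fasta(stats::setNames(cand_df$orf_aa, cand_df$candidate),
              file.path(config$out_dir, "candidate_orfs.faa"))
  files$candidate_orfs <- file.path(config$out_dir, "candidate_orfs.faa")
  if (!is.null(demarcation$matrix)) {
    mt <- data.frame(label = rownames(demarcation$matrix),
                     round(demarcation$matrix, 2), check.names = FALSE)
    files$identity <- file.path(config$out_dir, "identity_matrix.tsv")
    write_tsv(mt, files$identity)
    part_rows <- list()
    for (thr in config$demarcation_thresholds) {
      cl <- demarcation[[as.character(thr)]]
      for (k in seq_along(cl))
        part_rows[[length(part_rows) + 1L]] <- data.frame(
          threshold = thr, species = k,
          members = paste(cl[[k]], collapse = ","),
          stringsAsFactors = FALSE)
    }
    files$partitions <- file.path(config$out_dir, "species_partitions.tsv")
    write_tsv(do.call(rbind, part_rows), files$partitions)
    if (!is.null(demarcation$newick)) {
      files$tree <- file.path(config$out_dir, "candidates.nwk")
      writeLines(demarcation$newick, files$tree)
    }
  }
  log_lines <- c(log_lines,
                 sprintf("tiers: %s", paste(sprintf("%s=%d",
                         tier_summary$tier, tier_summary$count),
                         collapse = " ")),
                 sprintf("candidates: %d", nrow(cand_df)))
  writeLines(log_lines, files$log)
  invisible(list(triage = triage, tier_summary = tier_summary,
                 candidates = cand_df, demarcation = demarcation,
                 files = files))
}

#' Compare candidate proteins across libraries
#'
#' Reports every cross-library candidate pair whose global amino-acid
#' identity reaches the floor — the check that linked the partiti-like
#' viruses of two different cultures at 30% identity.
#'
#' @param candidates data.frame with `library`, `candidate`, `orf_aa`
#'   (e.g. rbind of `candidates` tables from [run_pipeline()] results,
#'   with a `library` column added).
#' @param floor Minimum percent identity to report (default 25).
#' @return data.frame of pairs: `library_a`, `candidate_a`, `library_b`,
#'   `candidate_b`, `identity`.
#' @export
cross_library_compare <- function(candidates, floor = 25) {
  out <- data.frame(library_a = character(), candidate_a = character(),
                    library_b = character(), candidate_b = character(),
                    identity = numeric(), stringsAsFactors = FALSE)
  n <- nrow(candidates)
  if (is.null(n) || n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (candidates$library[i] == candidates$library[j]) next
      idy <- global_identity(candidates$orf_aa[i], candidates$orf_aa[j])
      if (idy >= floor)
        out[nrow(out) + 1L, ] <- list(candidates$library[i],
                                      candidates$candidate[i],
                                      candidates$library[j],
                                      candidates$candidate[j],
                                      round(idy, 1))
    }
  }
  out
}
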