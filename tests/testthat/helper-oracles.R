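# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# --- six-frame stop-free region enumeration ------------------------------

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

oracle_translate_codon <- function(codon, tab) {
  if (grepl("[^ACGT]", codon)) return("X")
  unname(tab[codon])
}

# Enumerate every maximal stop-free codon run in all six frames, walking
# codon by codon (no rle/vectorised tricks).
oracle_find_orfs <- function(seq, code = 1, min_aa = 1) {
  tab <- Biostrings::getGeneticCode(as.character(code))
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") seq else oracle_revcomp(seq)
    for (frame in 0:2) {
      run_aa <- character(); run_start <- NA
      ncod <- (L - frame) %/% 3
      flush <- function(end_codon) {
        if (length(run_aa) >= min_aa) {
          rs <- frame + 3 * run_start
          re <- frame + 3 * end_codon
          if (strand == "+") {
            st <- rs; en <- re
          } else {
            st <- L - re; en <- L - rs
          }
          out[[length(out) + 1]] <<- list(
            strand = strand, start = st, end = en,
            aa = paste(run_aa, collapse = ""))
        }
      }
      if (ncod >= 1) {
        for (ci in 0:(ncod - 1)) {
          codon <- substr(w, frame + 3 * ci + 1, frame + 3 * ci + 3)
          aa <- oracle_translate_codon(codon, tab)
          if (aa == "*") {
            flush(ci)
            run_aa <- character(); run_start <- NA
          } else {
            if (is.na(run_start)) run_start <- ci
            run_aa <- c(run_aa, aa)
          }
        }
        flush(ncod)
      }
    }
  }
  out
}

orf_set_key <- function(df) {
  sort(sprintf("%s:%d-%d:%s", df$strand, df$start, df$end, df$aa_seq))
}

oracle_orf_key <- function(lst) {
  sort(vapply(lst, function(o)
    sprintf("%s:%d-%d:%s", o$strand, o$start, o$end, o$aa), character(1)))
}

# --- exhaustive local alignment (affine gaps) ----------------------------

# Enumerate every gapped alignment between every substring pair and score
# it with BLOSUM62 + affine penalties; return the best score found.
# Feasible only for sequences of a handful of residues.
oracle_sw <- function(q, t, gap_open = 11, gap_extend = 1) {
  b62 <- {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  }
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  best <- 0
  align_rec <- function(i, j, i2, j2, score, prev_gap) {
    # aligning q[i..i2], t[j..j2]; prev_gap in {"", "q", "t"}
    if (i > i2 && j > j2) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i <= i2 && j <= j2)
      align_rec(i + 1, j + 1, i2, j2, score + b62[qc[i], tc[j]], "")
    if (i <= i2)  # gap in target
      align_rec(i + 1, j, i2, j2,
                score - gap_extend - if (prev_gap == "t") 0 else gap_open,
                "t")
    if (j <= j2)  # gap in query
      align_rec(i, j + 1, i2, j2,
                score - gap_extend - if (prev_gap == "q") 0 else gap_open,
                "q")
    invisible()
  }
  nq <- length(qc); nt <- length(tc)
  for (i in 1:nq) for (i2 in i:nq) for (j in 1:nt) for (j2 in j:nt)
    align_rec(i, j, i2, j2, 0, "")
  best
}

# --- exhaustive profile-HMM path enumeration -----------------------------

# Enumerate all local paths (enter any match state, exit any match state,
# M/I/D core moves) and return the list of path scores in bits.
oracle_profile_paths <- function(profile, aa_seq) {
  idx <- match(strsplit(aa_seq, "")[[1]], rdrprospector:::AA_ALPHABET)
  n <- length(idx); L <- profile$length
  bgl <- profile$background
  msc <- (profile$match_emissions - rep(bgl, each = L)) / log(2)
  isc <- (profile$insert_emissions - rep(bgl, each = L)) / log(2)
  tb <- profile$transitions / log(2)
  scores <- numeric(0)
  # state: just consumed residue i at column k in state M or I, or sits
  # at column k in D
  recurse <- function(i, k, state, score) {
    if (state == "M") scores <<- c(scores, score)  # may exit here
    if (k >= L) return(invisible())
    trow <- k + 1  # transitions out of state k (row k+1, 1-based)
    if (state == "M") {
      if (i < n)  # M -> I (insert at column k)
        recurse(i + 1, k, "I", score + tb[trow, 2] + isc[k, idx[i + 1]])
      if (i < n)  # M -> M
        recurse(i + 1, k + 1, "M",
                score + tb[trow, 1] + msc[k + 1, idx[i + 1]])
      recurse(i, k + 1, "D", score + tb[trow, 3])  # M -> D
    } else if (state == "I") {
      if (i < n)  # I -> I
        recurse(i + 1, k, "I", score + tb[trow, 5] + isc[k, idx[i + 1]])
      if (i < n)  # I -> M
        recurse(i + 1, k + 1, "M",
                score + tb[trow, 4] + msc[k + 1, idx[i + 1]])
    } else {  # D
      if (i < n)  # D -> M
        recurse(i + 1, k + 1, "M",
                score + tb[trow, 6] + msc[k + 1, idx[i + 1]])
      recurse(i, k + 1, "D", score + tb[trow, 7])  # D -> D
    }
    invisible()
  }
  for (i in seq_len(n)) {
    for (k in seq_len(L)) {
      recurse(i, k, "M", msc[k, idx[i]])
    }
  }
  scores
}

oracle_viterbi <- function(profile, aa_seq) {
  max(0, oracle_profile_paths(profile, aa_seq))
}

oracle_forward <- function(profile, aa_seq) {
  s <- oracle_profile_paths(profile, aa_seq)
  log2(1 + sum(2^s))
}

# Small random profile for oracle comparisons.
make_toy_profile <- function(L, seed) {
  set.seed(seed)
  rdirich <- function(n) { x <- stats::rgamma(n, 1); x / sum(x) }
  me <- t(vapply(seq_len(L), function(k) log(rdirich(20)), numeric(20)))
  ie <- t(vapply(seq_len(L), function(k) log(rdirich(20)), numeric(20)))
  tr <- matrix(NA_real_, L + 1, 7)
  for (r in seq_len(L + 1)) {
    m3 <- rdirich(3); i2 <- rdirich(2); d2 <- rdirich(2)
    tr[r, ] <- log(c(m3, i2, d2))
  }
  profile_hmm(sprintf("toy_%d_%d", L, seed), me, ie, tr)
}

random_aa <- function(n) {
  paste(sample(rdrprospector:::AA_ALPHABET, n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
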