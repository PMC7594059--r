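#' Build a protein profile from a single seed sequence
#'
#' Constructs a plan7-style profile whose match states are centred on the
#' residues of a seed protein, with substitution tolerance borrowed from
#' BLOSUM62: the emission probability of residue `a` at a column whose
#' seed residue is `b` is proportional to `bg(a) * 2^(B62[a,b]/2)`. This
#' gives roughly half-bit-BLOSUM match scores, enough to recognise
#' homologs down to ~25-40% identity, the regime where divergent viral
#' RdRps live.
#'
#' @param protein Amino-acid string (length >= 2).
#' @param name Profile name.
#' @param class Profile class: `"rdrp_viral"` for the RdRp screen or
#'   `"decoy"` for false-positive control profiles.
#' @param match_prob Probability mass governing core transitions:
#'   MM = 0.97, MI = 0.02, MD = 0.01 by default.
#' @return A [profile_hmm] with a `profile_class` field.
#' @export
profile_from_protein <- function(protein, name, class = "rdrp_viral",
                                 match_prob = c(MM = 0.97, MI = 0.02, MD = 0.01)) {
  idx <- aa_encode(protein)
  idx <- idx[!is.na(idx)]
  L <- length(idx)
  if (L < 2) stop("seed protein must have >= 2 standard residues")
  bg <- amino_background()
  b62 <- blosum62_matrix()[AA_ALPHABET, AA_ALPHABET]
  match_em <- matrix(NA_real_, L, 20)
  for (k in seq_len(L)) {
    w <- bg * 2^(b62[, idx[k]] / 2)
    match_em[k, ] <- log(w / sum(w))
  }
  ins_em <- matrix(rep(log(bg), each = L), L, 20)
  tr <- matrix(-Inf, L + 1, 7)
  core <- log(c(match_prob[["MM"]], match_prob[["MI"]], match_prob[["MD"]],
                0.9, 0.1, 0.9, 0.1))
  for (r in seq_len(L)) tr[r, ] <- core
  # final match state: no delete continuation
  tr[L + 1, ] <- c(log(0.98), log(0.02), -Inf, log(0.9), log(0.1), 0, -Inf)
  p <- profile_hmm(name, match_em, ins_em, tr, background = log(bg))
  p$profile_class <- class
  p
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

profile_class_of <- function(profile) {
  cls <- profile$profile_class
  if (is.null(cls))
    cls <- if (grepl("^decoy", profile$name)) "decoy" else "rdrp_viral"
  cls
}

# Precompute bit-space log-odds inputs for the DP engine.
profile_bits <- function(profile, seq_idx) {
  n <- length(seq_idx)
  L <- profile$length
  lodds_m <- (profile$match_emissions -
                rep(profile$background, each = L)) / log(2)
  lodds_i <- (profile$insert_emissions -
                rep(profile$background, each = L)) / log(2)
  msc <- matrix(0, n, L)
  isc <- matrix(0, n, L)
  known <- !is.na(seq_idx)
  if (any(known)) {
    msc[known, ] <- lodds_m[, seq_idx[known], drop = FALSE] |> t()
    isc[known, ] <- lodds_i[, seq_idx[known], drop = FALSE] |> t()
  }
  list(msc = msc, isc = isc, tb = profile$transitions / log(2))
}

#' Viterbi score of a sequence against a profile
#'
#' Local (free entry/exit into match states) Viterbi alignment of an
#' amino-acid sequence to a profile, scored in bits as log-odds against
#' the profile's background. The empty alignment scores 0, so scores are
#' nonnegative.
#'
#' @param profile A [profile_hmm].
#' @param aa_seq Amino-acid string.
#' @return List: `score` (bits), `q_start`, `q_end`, `p_start`, `p_end`
#'   (0-based half-open matched intervals on the query and the profile).
#' @export
viterbi_score <- function(profile, aa_seq) {
  if (!inherits(profile, "profile_hmm")) stop("profile must be a profile_hmm")
  idx <- aa_encode(aa_seq)
  if (!length(idx)) stop("empty query sequence")
  pb <- profile_bits(profile, idx)
  cpp_profile_viterbi(pb$msc, pb$isc, pb$tb)
}

#' Forward score of a sequence against a profile
#'
#' Log-sum-exp analogue of [viterbi_score()] over the same local path
#' set; always at least the Viterbi score.
#'
#' @inheritParams viterbi_score
#' @return Forward log-odds score in bits.
#' @export
forward_score <- function(profile, aa_seq) {
  if (!inherits(profile, "profile_hmm")) stop("profile must be a profile_hmm")
  idx <- aa_encode(aa_seq)
  if (!length(idx)) stop("empty query sequence")
  pb <- profile_bits(profile, idx)
  cpp_profile_forward(pb$msc, pb$isc, pb$tb)
}

#' Calibrate a profile against a shuffled-sequence null
#'
#' Scores `n` background-sampled random sequences with Viterbi and fits a
#' Gumbel distribution by the method of moments. The fitted
#' `(lambda, tau)` are stored in the profile and used to convert bit
#' scores to e-values.
#'
#' @param profile A [profile_hmm].
#' @param n Number of null sequences (default 200).
#' @param len Null sequence length (default 350, a typical ORF).
#' @param seed Integer seed.
#' @return The profile with `calibration` set.
#' @export
calibrate_profile <- function(profile, n = 200, len = 350, seed = 1) {
  bg <- exp(profile$background)
  scores <- with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- paste0(sample(AA_ALPHABET, len, replace = TRUE, prob = bg),
                  collapse = "")
      viterbi_score(profile, s)$score
    }, numeric(1))
  })
  lambda <- pi / (stats::sd(scores) * sqrt(6))
  tau <- mean(scores) - 0.5772156649 / lambda
  profile$calibration <- c(lambda = lambda, tau = tau)
  profile
}

# Gumbel tail probability for a calibrated score.
profile_pvalue <- function(profile, score) {
  if (is.null(profile$calibration)) return(NA_real_)
  lambda <- profile$calibration[["lambda"]]
  tau <- profile$calibration[["tau"]]
  -expm1(-exp(-lambda * (score - tau)))
}

# Permutation-null p-value: rank of the observed score among scores of
# residue-shuffled copies of the query (fallback when uncalibrated).
shuffle_pvalue <- function(profile, aa_seq, score, n = 200, seed = 1) {
  chars <- strsplit(aa_seq, "")[[1]]
  null <- with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      viterbi_score(profile, paste0(sample(chars), collapse = ""))$score
    }, numeric(1))
  })
  (1 + sum(null >= score)) / (n + 1)
}

# Run code under a temporary RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
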