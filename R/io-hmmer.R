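#' Profile hidden Markov models
#'
#' A `profile_hmm` is a plan7-style protein profile: per-match-state
#' emission distributions over the 20 amino acids, per-state insert
#' emissions, and the seven per-state transitions (MM, MI, MD, IM, II,
#' DM, DD). All probabilities are stored as natural logarithms.
#' `calibration`, when present, holds Gumbel parameters `(lambda, tau)`
#' fitted to a shuffled-sequence null, used to convert bit scores to
#' e-values.
#'
#' @param name Model name.
#' @param match_emissions L x 20 matrix of log probabilities (columns in
#'   [AA_ALPHABET] order).
#' @param insert_emissions L x 20 matrix of log probabilities.
#' @param transitions (L+1) x 7 matrix of log probabilities, rows for
#'   states 0 (begin) .. L, columns MM, MI, MD, IM, II, DM, DD.
#' @param background Length-20 vector of log background probabilities.
#' @param calibration `NULL` or named vector `c(lambda=, tau=)`.
#' @return Object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emissions, insert_emissions,
                        transitions, background = log(amino_background()),
                        calibration = NULL) {
  L <- nrow(match_emissions)
  stopifnot(L >= 1, ncol(match_emissions) == 20,
            nrow(insert_emissions) == L, ncol(insert_emissions) == 20,
            nrow(transitions) == L + 1, ncol(transitions) == 7,
            length(background) == 20)
  colnames(match_emissions) <- AA_ALPHABET
  colnames(insert_emissions) <- AA_ALPHABET
  colnames(transitions) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  obj <- structure(list(
    name = name, alphabet = "amino", length = L,
    match_emissions = match_emissions,
    insert_emissions = insert_emissions,
    transitions = transitions,
    background = stats::setNames(background, AA_ALPHABET),
    calibration = calibration
  ), class = "profile_hmm")
  validate_profile_hmm(obj)
  obj
}

validate_profile_hmm <- function(p, tol = 1e-6) {
  chk <- function(m, what) {
    s <- rowSums(exp(m))
    if (any(abs(s - 1) > tol))
      stop("profile '", p$name, "': ", what,
           " distribution does not normalise (max dev ",
           signif(max(abs(s - 1)), 3), ")")
  }
  chk(p$match_emissions, "match emission")
  chk(p$insert_emissions, "insert emission")
  tr <- exp(p$transitions)
  groups <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
  for (g in groups) {
    s <- rowSums(tr[, g, drop = FALSE])
    # final state has truncated MD/DD; allow rows that renormalise over
    # the available transitions
    if (any(abs(s - 1) > tol))
      stop("profile '", p$name, "': transition group ",
           paste(g, collapse = "/"), " does not normalise")
  }
  if (abs(sum(exp(p$background)) - 1) > tol)
    stop("profile '", p$name, "': background does not normalise")
  invisible(p)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$name, "': ", x$length, " match states, amino",
      if (is.null(x$calibration)) ", uncalibrated" else ", calibrated",
      "\n", sep = "")
  invisible(x)
}

num_or_star <- function(x) {
  # HMMER3 text stores -log(p); '*' means p = 0
  out <- rep(-Inf, length(x))
  num <- x != "*"
  out[num] <- -as.numeric(x[num])
  out
}

# Text profiles are rounded to ~5 decimals; check the stored values are a
# distribution to coarse tolerance, then renormalise exactly so downstream
# invariants hold at 1e-6.
renorm_log <- function(lp, what, where, tol = 1e-3) {
  s <- sum(exp(lp))
  if (s == 0) stop(where, ": ", what, " distribution is all-zero")
  if (abs(s - 1) > tol)
    stop(where, ": ", what, " distribution sums to ", signif(s, 6),
         ", not 1")
  lp - log(s)
}

#' Parse profiles from a HMMER3 text file
#'
#' Reads one or more protein profiles from a HMMER3/f-dialect text file:
#' negative-natural-log emission and transition scores, `*` for zero
#' probability, optional `COMPO` average-composition line (used as the
#' background when present) and optional `STATS LOCAL VITERBI tau lambda`
#' calibration line.
#'
#' @param path Path to the profile file (may contain multiple models,
#'   each terminated by `//`).
#' @return List of [profile_hmm] objects in file order.
#' @export
parse_hmmer3_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  models <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    # seek header
    while (i <= n && !grepl("^HMMER3", lines[i])) {
      if (grepl("\\S", lines[i]))
        stop("line ", i, ": expected HMMER3 header, got: ", lines[i])
      i <- i + 1L
    }
    if (i > n) break
    hdr <- list(name = NULL, leng = NULL, alph = NULL, calib = NULL,
                class = NULL)
    i <- i + 1L
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) >= 2) {
        key <- f[1]
        if (key == "NAME") hdr$name <- f[2]
        if (key == "LENG") hdr$leng <- as.integer(f[2])
        if (key == "ALPH") hdr$alph <- tolower(f[2])
        if (key == "CLASS") hdr$class <- f[2]
        if (key == "STATS" && length(f) >= 5 && f[2] == "LOCAL" &&
            f[3] == "VITERBI")
          hdr$calib <- c(lambda = as.numeric(f[5]), tau = as.numeric(f[4]))
      }
      i <- i + 1L
    }
    if (i > n) stop("line ", i, ": missing HMM line")
    if (is.null(hdr$name)) stop("model at line ", i, ": missing NAME line")
    if (is.null(hdr$leng)) stop("model '", hdr$name, "': missing LENG line")
    if (is.null(hdr$alph)) stop("model '", hdr$name, "': missing ALPH line")
    if (hdr$alph != "amino")
      stop("model '", hdr$name, "': unsupported alphabet '", hdr$alph,
           "' (only amino profiles are supported)")
    # HMM line carries the residue order
    res_order <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
    if (length(res_order) != 20)
      stop("line ", i, ": expected 20 residues on HMM line")
    perm <- match(AA_ALPHABET, res_order)
    if (anyNA(perm)) stop("line ", i, ": HMM residue order is not amino")
    i <- i + 2L  # skip transition-name header line
    background <- log(amino_background())
    if (grepl("^\\s*COMPO\\s", lines[i])) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      bg <- num_or_star(f[2:21])[perm]
      bg <- bg - log(sum(exp(bg)))  # normalise stored composition
      background <- bg
      i <- i + 1L
    }
    L <- hdr$leng
    ins0 <- num_or_star(strsplit(trimws(lines[i]), "\\s+")[[1]][1:20])[perm]
    i <- i + 1L
    tr0 <- num_or_star(strsplit(trimws(lines[i]), "\\s+")[[1]][1:7])
    i <- i + 1L
    match_em <- matrix(NA_real_, L, 20)
    ins_em <- matrix(NA_real_, L, 20)
    trans <- matrix(-Inf, L + 1L, 7)
    trans[1L, ] <- tr0
    for (k in seq_len(L)) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (as.integer(f[1]) != k)
        stop("line ", i, ": expected match state ", k, ", got ", f[1])
      match_em[k, ] <- num_or_star(f[2:21])[perm]
      i <- i + 1L
      ins_em[k, ] <- num_or_star(
        strsplit(trimws(lines[i]), "\\s+")[[1]][1:20])[perm]
      i <- i + 1L
      trans[k + 1L, ] <- num_or_star(
        strsplit(trimws(lines[i]), "\\s+")[[1]][1:7])
      i <- i + 1L
    }
    if (i > n || !grepl("^//", lines[i]))
      stop("line ", i, ": expected '//' terminator for model '",
           hdr$name, "'")
    i <- i + 1L
    where <- paste0("model '", hdr$name, "'")
    for (k in seq_len(L)) {
      match_em[k, ] <- renorm_log(match_em[k, ], "match emission", where)
      ins_em[k, ] <- renorm_log(ins_em[k, ], "insert emission", where)
    }
    for (r in seq_len(L + 1L)) {
      for (g in list(1:3, 4:5, 6:7)) {
        if (all(is.infinite(trans[r, g]))) {
          trans[r, g[1]] <- 0  # truncated group (e.g. begin-state deletes)
        } else {
          trans[r, g] <- renorm_log(trans[r, g], "transition", where)
        }
      }
    }
    # insert0 row is not carried in the profile_hmm container; the first
    # insert state's emissions stand in for it in local alignment
    p <- profile_hmm(
      name = hdr$name,
      match_emissions = match_em,
      insert_emissions = ins_em,
      transitions = trans,
      background = background,
      calibration = hdr$calib
    )
    if (!is.null(hdr$class)) p$profile_class <- hdr$class
    models[[length(models) + 1L]] <- p
  }
  if (!length(models)) stop("no HMMER3 models found in ", path)
  models
}

fmt_neglog <- function(x) {
  ifelse(is.infinite(x), "*", sprintf("%8.5f", -x))
}

#' Write profiles to a HMMER3-dialect text file
#'
#' Emits the same negative-natural-log text layout that
#' [parse_hmmer3_profile()] reads, including a `COMPO` background line and
#' a `STATS LOCAL VITERBI` line when the profile is calibrated.
#'
#' @param profiles A [profile_hmm] or list of them.
#' @param path Output path.
#' @export
write_hmmer3_profile <- function(profiles, path) {
  if (inherits(profiles, "profile_hmm")) profiles <- list(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    L <- p$length
    cat("HMMER3/f [rdrprospector profile dialect]\n", file = con)
    cat("NAME  ", p$name, "\n", sep = "", file = con)
    cat("LENG  ", L, "\n", sep = "", file = con)
    cat("ALPH  amino\n", file = con)
    if (!is.null(p$profile_class))
      cat("CLASS ", p$profile_class, "\n", sep = "", file = con)
    if (!is.null(p$calibration))
      cat(sprintf("STATS LOCAL VITERBI %10.5f %10.5f\n",
                  p$calibration[["tau"]], p$calibration[["lambda"]]),
          file = con)
    cat("HMM     ", paste(sprintf("%8s", AA_ALPHABET), collapse = " "),
        "\n", sep = "", file = con)
    cat("        ", paste(sprintf("%8s",
        c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
        collapse = " "), "\n", sep = "", file = con)
    cat("  COMPO ", paste(fmt_neglog(p$background), collapse = " "),
        "\n", sep = "", file = con)
    cat("        ", paste(fmt_neglog(p$insert_emissions[1, ]),
                          collapse = " "), "\n", sep = "", file = con)
    cat("        ", paste(fmt_neglog(p$transitions[1, ]), collapse = " "),
        "\n", sep = "", file = con)
    for (k in seq_len(L)) {
      cat(sprintf("%7d ", k),
          paste(fmt_neglog(p$match_emissions[k, ]), collapse = " "),
          "\n", sep = "", file = con)
      cat("        ", paste(fmt_neglog(p$insert_emissions[k, ]),
                            collapse = " "), "\n", sep = "", file = con)
      cat("        ", paste(fmt_neglog(p$transitions[k + 1, ]),
                            collapse = " "), "\n", sep = "", file = con)
    }
    cat("//\n", file = con)
  }
  invisible(path)
}
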