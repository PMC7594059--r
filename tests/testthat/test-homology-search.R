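test_that("self-alignment raw score equals the BLOSUM62 diagonal sum", {
  set.seed(8)
  q <- random_aa(50)
  h <- local_align(q, q)
  b62 <- rdrprospector:::blosum62_matrix()
  diag_sum <- sum(vapply(strsplit(q, "")[[1]],
                         function(a) b62[a, a], numeric(1)))
  expect_equal(h$raw_score, diag_sum)
  expect_equal(h$q_start, 0)
  expect_equal(h$q_end, 50)
  expect_true(h$e_value < 1e-10)
})

test_that("Smith-Waterman matches exhaustive enumeration on tiny pairs", {
  set.seed(12)
  for (rep in 1:25) {
    q <- random_aa(sample(2:6, 1))
    t <- random_aa(sample(2:6, 1))
    got <- local_align(q, t)$raw_score
    expect_equal(got, oracle_sw(q, t), info = paste(q, t))
  }
})

test_that("appending residues never decreases the local score", {
  set.seed(13)
  for (rep in 1:20) {
    q <- random_aa(sample(5:20, 1))
    t <- random_aa(sample(5:20, 1))
    s0 <- local_align(q, t)$raw_score
    s1 <- local_align(paste0(q, random_aa(5)), t)$raw_score
    expect_true(s1 >= s0)
  }
})

test_that("reference search against an empty set returns no hits", {
  empty_ref <- data.frame(id = character(), seq = character(),
                          label = character(), stringsAsFactors = FALSE)
  h <- search_reference(c(q1 = random_aa(30)), empty_ref)
  expect_equal(nrow(h), 0)
  expect_error(local_align("", "ACD"), "empty")
  expect_error(local_align("ACD", "ACD", gap_open = -1), "positive")
})

test_that("profile Viterbi and forward match path enumeration on toy models", {
  for (seed in 1:12) {
    L <- sample(2:4, 1)
    p <- make_toy_profile(L, seed)
    s <- random_aa(sample(2:4, 1))
    v <- viterbi_score(p, s)
    expect_equal(v$score, oracle_viterbi(p, s), tolerance = 1e-9,
                 info = sprintf("viterbi L=%d seed=%d", L, seed))
    expect_equal(forward_score(p, s), oracle_forward(p, s),
                 tolerance = 1e-9,
                 info = sprintf("forward L=%d seed=%d", L, seed))
  }
})

test_that("forward dominates Viterbi on random profile/sequence pairs", {
  set.seed(77)
  for (rep in 1:100) {
    p <- make_toy_profile(sample(2:6, 1), 1000 + rep)
    s <- random_aa(sample(2:10, 1))
    expect_true(forward_score(p, s) >= viterbi_score(p, s)$score - 1e-9)
  }
})

test_that("profile-consensus sequences outscore their shuffles", {
  src <- rdrp_exemplar(4, length = 120)
  p <- profile_from_protein(src, "cons_test")
  for (seed in 1:20) {
    set.seed(seed)
    shuf <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
    expect_true(viterbi_score(p, src)$score > viterbi_score(p, shuf)$score)
  }
})

test_that("calibrated e-values favour true homologs over shuffles", {
  src <- rdrp_exemplar(5, length = 80)
  p <- calibrate_profile(profile_from_protein(src, "cal_test"),
                         n = 100, len = 80, seed = 3)
  wins <- 0
  for (rep in 1:100) {
    hom <- mutate_protein(src, 60, seed = 5000 + rep)
    set.seed(rep)
    shuf <- paste(sample(strsplit(hom, "")[[1]]), collapse = "")
    e_hom <- rdrprospector:::profile_pvalue(p, viterbi_score(p, hom)$score)
    e_shuf <- rdrprospector:::profile_pvalue(p, viterbi_score(p, shuf)$score)
    if (e_hom <= e_shuf) wins <- wins + 1
  }
  expect_true(wins >= 95)
})

test_that("ORF scanning ranks the right profile family first", {
  expect_equal(nrow(scan_orfs(c(o1 = random_aa(50)), list())), 0)
  rdrp_src <- rdrp_exemplar(1)
  phage_src <- rdrprospector:::phage_decoy_proteins(1)[[1]]
  profs <- list(
    profile_from_protein(rdrp_src, "rdrp_profile_x", class = "rdrp_viral"),
    profile_from_protein(phage_src, "decoy_phage_x", class = "decoy"))
  planted <- mutate_protein(rdrp_src, 60, seed = 2)
  h <- scan_orfs(c(orf1 = planted), profs)
  expect_equal(h$profile_class[1], "rdrp_viral")
  decoy_like <- mutate_protein(phage_src, 70, seed = 3)
  h2 <- scan_orfs(c(orf2 = decoy_like), profs)
  expect_equal(h2$profile_class[1], "decoy")
  # uncalibrated profiles + shuffle null produce usable e-values
  h3 <- scan_orfs(c(orf1 = planted), profs[1], shuffle_null = TRUE,
                  n_shuffle = 30, seed = 4)
  expect_true(is.finite(h3$e_value[1]))
  expect_true(h3$e_value[1] < 0.5)
})

test_that("motif scanning finds A/B/C architectures and flags variants", {
  core <- function(cmotif)
    paste0(random_aa(40), "DAPKD", random_aa(30), "GLMN",
           random_aa(20), cmotif, random_aa(30))
  set.seed(30)
  ann <- scan_motifs(core("AGDDK"))
  expect_false(is.null(ann$motifA))
  expect_false(is.null(ann$motifB))
  expect_equal(ann$motifC$match, "GDD")
  expect_true(ann$motifC_canonical)
  expect_true(ann$motifA$start < ann$motifB$start)
  expect_true(ann$motifB$start < ann$motifC$start)
  # noncanonical GFD: located but not canonical
  set.seed(31)
  ann2 <- scan_motifs(core("AGFDK"))
  expect_equal(ann2$motifC_variant, "GFD")
  expect_false(ann2$motifC_canonical)
  # absent motifs stay NULL
  ann3 <- scan_motifs(strrep("K", 60))
  expect_null(ann3$motifC)
  expect_null(ann3$motifA)
})

test_that("canonical motif C is rare in shuffled RdRps", {
  src <- rdrp_exemplar(1)
  chars <- strsplit(src, "")[[1]]
  hits <- 0
  for (rep in 1:100) {
    set.seed(rep)
    shuf <- paste(sample(chars), collapse = "")
    ann <- scan_motifs(shuf)
    if (!is.null(ann$motifC) && ann$motifC_canonical) hits <- hits + 1
  }
  expect_true(hits < 50)
})
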