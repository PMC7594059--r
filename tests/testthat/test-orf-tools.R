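test_that("ORF finder recovers the textbook example and matches brute force", {
  o <- find_orfs(list(id = "c1", seq = "ATGAAATAA"), code = 1, min_aa = 1)
  fwd0 <- o[o$strand == "+" & o$frame == 0, ]
  expect_equal(nrow(fwd0), 1)
  expect_equal(fwd0$aa_seq, "MK")
  expect_equal(fwd0$start, 0)
  expect_equal(fwd0$end, 6)
  expect_identical(orf_set_key(o),
                   oracle_orf_key(oracle_find_orfs("ATGAAATAA", 1, 1)))
})

test_that("ORF finder equals six-frame brute-force enumeration on random contigs", {
  set.seed(11)
  for (rep in 1:60) {
    len <- sample(30:600, 1)
    seq <- random_dna_str(len)
    code <- sample(c(1, 4), 1)
    min_aa <- sample(c(1, 5, 20), 1)
    got <- find_orfs(list(id = "r", seq = seq), code = code, min_aa = min_aa)
    want <- oracle_find_orfs(seq, code, min_aa)
    expect_identical(orf_set_key(got), oracle_orf_key(want),
                     info = sprintf("len=%d code=%d min=%d", len, code, min_aa))
  }
})

test_that("reverse complement gives mirrored ORFs with swapped strands", {
  set.seed(5)
  for (rep in 1:20) {
    seq <- random_dna_str(sample(60:400, 1))
    L <- nchar(seq)
    a <- find_orfs(list(id = "x", seq = seq), min_aa = 5)
    b <- find_orfs(list(id = "x", seq = revcomp(seq)), min_aa = 5)
    mirrored <- sprintf("%s:%d-%d:%s",
                        ifelse(b$strand == "+", "-", "+"),
                        L - b$end, L - b$start, b$aa_seq)
    expect_identical(orf_set_key(a), sort(mirrored))
  }
})

test_that("coordinates round-trip: slicing and translating reproduces aa_seq", {
  set.seed(21)
  for (rep in 1:15) {
    seq <- random_dna_str(sample(90:500, 1))
    L <- nchar(seq)
    orfs <- find_orfs(list(id = "x", seq = seq), code = 4, min_aa = 5)
    for (i in seq_len(nrow(orfs))) {
      sl <- substr(seq, orfs$start[i] + 1, orfs$end[i])
      if (orfs$strand[i] == "-") sl <- revcomp(sl)
      expect_equal(translate_dna(sl, 4), orfs$aa_seq[i])
    }
  }
})

test_that("genetic code 4 reads through TGA while code 1 splits the region", {
  # MW (TGG TGA) under code 4 is one region; code 1 stops at TGA
  seq <- paste0("ATGTGGTGATGGAAA")  # M W * W K  (code 1) / M W W W K (code 4)
  o1 <- find_orfs(list(id = "t", seq = seq), code = 1, min_aa = 1)
  o4 <- find_orfs(list(id = "t", seq = seq), code = 4, min_aa = 1)
  f1 <- o1[o1$strand == "+" & o1$frame == 0, ]
  f4 <- o4[o4$strand == "+" & o4$frame == 0, ]
  expect_setequal(f1$aa_seq, c("MW", "WK"))
  expect_equal(f4$aa_seq, "MWWWK")
})

test_that("N-containing codons translate to X and never terminate a region", {
  seq <- "ATGNNNAAATAA"
  o <- find_orfs(list(id = "n", seq = seq), code = 1, min_aa = 1)
  f0 <- o[o$strand == "+" & o$frame == 0, ]
  expect_equal(f0$aa_seq, "MXK")
  expect_false(grepl("\\*", f0$aa_seq))
})

test_that("unknown genetic code and short contigs are rejected", {
  expect_error(find_orfs(list(id = "x", seq = "ATGAAATAA"), code = 2),
               "unknown genetic code")
  expect_error(find_orfs(list(id = "x", seq = "AT")), "length")
})

test_that("slippery-site detection finds GGATTTT on both strands", {
  expect_equal(nrow(detect_slippery_sites(list(id = "a", seq = "ACGTACGTACGT"))), 0)
  seq <- paste0(strrep("C", 12), "GGATTTT", strrep("A", 6))
  d <- detect_slippery_sites(list(id = "b", seq = seq))
  expect_equal(d$pos, 12)
  expect_equal(d$strand, "+")
  # reverse strand occurrence: plant revcomp of the heptamer
  seq2 <- paste0(strrep("C", 5), revcomp("GGATTTT"), strrep("G", 4))
  d2 <- detect_slippery_sites(list(id = "c", seq = seq2))
  expect_equal(d2$pos, 5)
  expect_equal(d2$strand, "-")
})

test_that("frameshift fusion reproduces the planted replicase", {
  vp <- virus_plan("fsv", rdrp_source = 2, target_identity = 55,
                   genome_architecture = "two_orf_frameshift",
                   genome_length = 2600, read_count = 10)
  pv <- plant_viral_contig(vp, seed = 9)
  ctg <- pv$contig
  slip <- pv$truth$slip_pos
  d <- detect_slippery_sites(ctg)
  expect_true(slip %in% d$pos)
  orfs <- find_orfs(ctg, code = 1, min_aa = 30)
  covers <- function(o, pos) o$strand == "+" & o$start <= pos & o$end >= pos + 7
  cand1 <- orfs[covers(orfs, slip), ]
  # ORF1 frame contains the heptamer start at a codon boundary offset
  orf1 <- cand1[(slip - cand1$start) %% 3 == 0, ][1, ]
  orf2 <- cand1[(cand1$start - orf1$start) %% 3 == 2, ][1, ]
  expect_false(is.na(orf1$start))
  expect_false(is.na(orf2$start))
  fused <- join_frameshift_orfs(orf1, orf2, slip)
  expect_equal(fused$fused_aa, pv$truth$rdrp_aa)
  # heptamer lies inside the overlap of the two ORFs
  expect_true(max(orf1$start, orf2$start) <= slip &&
                slip + 7 <= min(orf1$end, orf2$end))
})

test_that("frameshift fusion rejects wrong frames and missing heptamers", {
  orf1 <- data.frame(contig_id = "c", strand = "+", frame = 0, start = 0,
                     end = 300, aa_seq = strrep("A", 100),
                     genetic_code = 1, partial5 = FALSE, partial3 = FALSE,
                     orf_id = "o1", stringsAsFactors = FALSE)
  plus1 <- orf1; plus1$start <- 151; plus1$end <- 451
  plus1$orf_id <- "o2"  # +1 frame relative to orf1
  expect_error(join_frameshift_orfs(orf1, plus1, 160), "-1 frame")
  minus1 <- orf1; minus1$start <- 200; minus1$end <- 500
  minus1$orf_id <- "o3"  # -1 frame but overlap [200,300) misses slip 300
  expect_error(join_frameshift_orfs(orf1, minus1, 295), "overlap")
})
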