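test_that("protein mutation hits the identity target", {
  p <- random_aa(300)
  expect_identical(mutate_protein(p, 100, seed = 5), p)
  m <- mutate_protein(p, 30, seed = 7)
  idy <- 100 * mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
  expect_true(idy >= 28 && idy <= 32)
  p20 <- random_aa(20)
  m20 <- mutate_protein(p20, 50, seed = 1)
  matches <- sum(strsplit(p20, "")[[1]] == strsplit(m20, "")[[1]])
  expect_true(abs(matches - 10) <= 1)
  expect_error(mutate_protein(p, 0, seed = 1), "target_identity")
  expect_error(mutate_protein(p, 101, seed = 1), "target_identity")
  expect_error(mutate_protein(random_aa(10), 50, seed = 1), ">= 20")
})

test_that("identity targeting holds within 2 points across 100 random plans", {
  set.seed(40)
  for (rep in 1:100) {
    L <- sample(50:400, 1)
    tgt <- stats::runif(1, 20, 95)
    p <- random_aa(L)
    m <- mutate_protein(p, tgt, seed = rep)
    idy <- 100 * mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
    expect_true(abs(idy - tgt) <= 2,
                info = sprintf("L=%d target=%.1f realized=%.1f", L, tgt, idy))
  }
})

test_that("protected positions survive mutation", {
  p <- rdrp_exemplar(1)
  m <- mutate_protein(p, 40, seed = 3,
                      protect = rdrprospector:::rdrp_exemplar_motifs())
  keep <- rdrprospector:::rdrp_exemplar_motifs()
  expect_identical(strsplit(m, "")[[1]][keep], strsplit(p, "")[[1]][keep])
})

test_that("single-ORF planting is recovered exactly by the ORF finder", {
  vp <- virus_plan("sv", rdrp_source = 1, target_identity = 70,
                   genome_architecture = "single_orf",
                   genome_length = 2400, read_count = 5)
  pv <- plant_viral_contig(vp, seed = 4)
  orfs <- find_orfs(pv$contig, code = 1, min_aa = 200)
  hit <- orfs[orfs$start == pv$truth$orf_start &
                orfs$end == pv$truth$orf_end & orfs$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$aa_seq, pv$truth$rdrp_aa)
})

test_that("frameshift genomes embed the slippery heptamer at the recorded overlap", {
  vp <- virus_plan("fv", rdrp_source = 2, target_identity = 50,
                   genome_architecture = "two_orf_frameshift",
                   genome_length = 2600, read_count = 5)
  pv <- plant_viral_contig(vp, seed = 6)
  slip <- pv$truth$slip_pos
  expect_equal(substr(pv$contig$seq, slip + 1, slip + 7), "GGATTTT")
  expect_true(slip %in% detect_slippery_sites(pv$contig)$pos)
})

test_that("protozoan mitochondrial genomes need code 4 for the full ORF", {
  # pick a seed whose back-translation uses TGA for at least one Trp
  found <- FALSE
  for (s in 1:10) {
    vp <- virus_plan("mv", rdrp_source = 1, target_identity = 80,
                     genome_architecture = "single_orf",
                     genetic_code = "protozoan_mitochondrial",
                     genome_length = 2400, read_count = 5)
    pv <- plant_viral_contig(vp, seed = s)
    orf_nt <- substr(pv$contig$seq, pv$truth$orf_start + 1, pv$truth$orf_end)
    cods <- substring(orf_nt, seq(1, nchar(orf_nt) - 2, 3),
                      seq(3, nchar(orf_nt), 3))
    if (!"TGA" %in% cods) next
    found <- TRUE
    expect_true(grepl("\\*", translate_dna(orf_nt, 1)))   # code 1 truncates
    expect_false(grepl("\\*", translate_dna(orf_nt, 4)))  # code 4 reads through
    expect_equal(translate_dna(orf_nt, 4), pv$truth$rdrp_aa)
    # the code-4 ORF set contains the full region; code 1 splits it
    o4 <- find_orfs(pv$contig, code = 4, min_aa = 50)
    expect_true(any(o4$start == pv$truth$orf_start &
                      o4$end == pv$truth$orf_end))
    o1 <- find_orfs(pv$contig, code = 1, min_aa = 1)
    expect_false(any(o1$start == pv$truth$orf_start &
                       o1$end == pv$truth$orf_end & o1$strand == "+"))
    break
  }
  expect_true(found)
})

test_that("architecture/length conflicts raise a generation error", {
  vp <- virus_plan("tiny", rdrp_source = 1, target_identity = 80,
                   genome_architecture = "single_orf",
                   genome_length = 300, read_count = 5)
  expect_error(plant_viral_contig(vp, seed = 1), "accommodate")
})

test_that("library generation is deterministic and truth-complete", {
  plan0 <- library_plan(n_host_contigs = 6, n_decoy_phage = 2,
                        n_rrna_like = 2, planted_viruses = list(),
                        total_non_rrna_reads = 1e5, seed = 3)
  lib0 <- generate_library(plan0)
  expect_equal(sum(lib0$truth$class == "virus"), 0)
  expect_equal(nrow(lib0$truth), nrow(lib0$contigs))
  plan <- library_plan(
    n_host_contigs = 6, n_decoy_phage = 2, n_rrna_like = 2,
    planted_viruses = list(
      virus_plan("va", 1, 80, "single_orf", genome_length = 2400,
                 read_count = 100),
      virus_plan("vb", 2, 40, "single_orf", genome_length = 2400,
                 read_count = 100),
      virus_plan("vc", 3, 20, "single_orf", genome_length = 2400,
                 read_count = 100)),
    total_non_rrna_reads = 1e5, seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  lib1 <- generate_library(plan, out_dir = d1)
  lib2 <- generate_library(plan, out_dir = d2)
  tv <- lib1$truth[lib1$truth$class == "virus", ]
  expect_setequal(tv$planted_identity, c(80, 40, 20))
  expect_identical(readLines(file.path(d1, "contigs.fasta")),
                   readLines(file.path(d2, "contigs.fasta")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  # one truth row per contig, ids unique
  expect_false(anyDuplicated(lib1$truth$contig_id) > 0)
  expect_setequal(lib1$truth$contig_id, lib1$contigs$id)
  # plan invariant: totals cover planted virus reads
  expect_error(library_plan(planted_viruses = list(
    virus_plan("big", 1, 80, read_count = 100)),
    total_non_rrna_reads = 10), "total_non_rrna_reads")
})
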