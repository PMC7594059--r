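test_that("global identity behaves on identical, near-identical and random pairs", {
  expect_equal(global_identity("ACDEFGHIK", "ACDEFGHIK"), 100)
  expect_equal(global_identity("ACDEFG", "ACDKFG"), 100 * 5 / 6,
               tolerance = 1e-9)
  set.seed(18)
  for (rep in 1:20) {
    a <- random_aa(sample(20:80, 1))
    b <- random_aa(sample(20:80, 1))
    expect_equal(global_identity(a, b), global_identity(b, a),
                 tolerance = 1e-9)
  }
  expect_error(global_identity("", "ACD"), "empty")
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  expect_equal(unname(identity_matrix(c(a = "ACDEF"))), matrix(100, 1, 1))
  set.seed(19)
  seqs <- stats::setNames(vapply(1:5, function(i) random_aa(40),
                                 character(1)), letters[1:5])
  m <- identity_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 5))
  expect_true(all(m >= 0 & m <= 100))
  # permuting the input permutes rows/columns consistently
  perm <- c(3, 1, 5, 2, 4)
  m2 <- identity_matrix(seqs[perm])
  expect_equal(m2, m[perm, perm])
})

test_that("planted divergence series is recovered within 3 identity points", {
  src <- rdrp_exemplar(1)
  targets <- c(90, 70, 50)
  muts <- vapply(seq_along(targets), function(i)
    mutate_protein(src, targets[i], seed = 100 + i), character(1))
  m <- identity_matrix(stats::setNames(c(src, muts),
                                       c("src", "t90", "t70", "t50")))
  for (i in seq_along(targets))
    expect_true(abs(m["src", i + 1] - targets[i]) <= 3,
                info = sprintf("target %d recovered %.1f", targets[i],
                               m["src", i + 1]))
})

test_that("threshold clustering follows single linkage", {
  m <- matrix(c(100, 95, 40,
                95, 100, 40,
                40, 40, 100), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl <- cluster_species(m, 90)
  expect_equal(cl, list(c("a", "b"), "c"))
  # threshold 100 with distinct sequences: singletons
  set.seed(20)
  seqs <- stats::setNames(vapply(1:4, function(i) random_aa(30),
                                 character(1)), paste0("s", 1:4))
  m2 <- identity_matrix(seqs)
  expect_equal(lengths(cluster_species(m2, 100)), rep(1L, 4))
  expect_error(cluster_species(m, 0), "threshold")
})

test_that("clustering is order-invariant and monotone in the threshold", {
  set.seed(22)
  n <- 8
  m <- matrix(stats::runif(n * n, 0, 100), n, n)
  m <- (m + t(m)) / 2; diag(m) <- 100
  dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
  canon <- function(cl) sort(vapply(cl, function(g)
    paste(sort(g), collapse = ","), character(1)))
  perm <- sample(n)
  expect_equal(canon(cluster_species(m, 60)),
               canon(cluster_species(m[perm, perm], 60)))
  for (thr in c(20, 40, 60, 80)) {
    lo <- cluster_species(m, thr)
    hi <- cluster_species(m, thr + 10)
    expect_true(length(hi) >= length(lo))  # raising threshold never merges
  }
})

test_that("seven mutually divergent narna-like RdRps form seven species at 50%", {
  set.seed(23)
  seqs <- stats::setNames(vapply(1:7, function(i) random_aa(200),
                                 character(1)), paste0("narna", 1:7))
  m <- identity_matrix(seqs)
  expect_true(all(m[upper.tri(m)] < 50))
  expect_equal(length(cluster_species(m, 50)), 7)
})

test_that("species partitions are exact when identities straddle the threshold", {
  src1 <- rdrp_exemplar(1); src2 <- rdrp_exemplar(2)
  # two species: within-species >= 95, between far below 90
  seqs <- c(a1 = src1, a2 = mutate_protein(src1, 96, seed = 1),
            b1 = src2, b2 = mutate_protein(src2, 96, seed = 2))
  cl <- cluster_species(identity_matrix(seqs), 90)
  canon <- sort(vapply(cl, function(g) paste(sort(g), collapse = ","),
                       character(1)))
  expect_equal(canon, c("a1,a2", "b1,b2"))
})

test_that("rank placement separates intra-genus members from new genera", {
  intra <- c(60, 65, 70, 75, 80)
  inter <- c(20, 25, 30, 35)
  expect_equal(place_rank(70, intra, inter)$verdict, "existing_taxon")
  expect_equal(place_rank(28, intra, inter)$verdict, "new_genus_candidate")
  expect_equal(place_rank(99, intra, inter)$verdict, "existing_taxon")
  # below every inter-genus sample is certainly a new-genus candidate
  expect_equal(place_rank(10, intra, inter)$verdict, "new_genus_candidate")
  s <- place_rank(70, intra, inter)$summary
  expect_equal(s$distribution, c("query", "intra", "inter"))
  expect_equal(s$min[s$distribution == "intra"], 60)
  expect_error(place_rank(50, numeric(0), inter), "nonempty")
})

test_that("neighbor joining recovers additive trees", {
  # 4-taxon additive matrix from tree ((A:2,B:3):1,(C:4,D:5):1)
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 8
  d["A", "D"] <- d["D", "A"] <- 9
  d["B", "C"] <- d["C", "B"] <- 9
  d["B", "D"] <- d["D", "B"] <- 10
  d["C", "D"] <- d["D", "C"] <- 9
  nwk <- nj_tree(d, is_distance = TRUE)
  tr <- ape::read.tree(text = nwk)
  # path-length matrix reproduces the input
  pd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(pd), unname(d), tolerance = 1e-6)
  # topology: A,B sister to C,D
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")) ||
                ape::is.monophyletic(ape::unroot(tr), c("C", "D")))
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- ape::read.tree(text = nj_tree(d3, is_distance = TRUE))
  bl <- stats::setNames(tr3$edge.length,
                        tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[["x"]], (4 + 6 - 8) / 2)
  expect_equal(bl[["y"]], (4 + 8 - 6) / 2)
  expect_equal(bl[["z"]], (6 + 8 - 4) / 2)
  # identical sequences: zero-length tree
  m <- matrix(100, 3, 3, dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  trz <- ape::read.tree(text = nj_tree(m))
  expect_equal(sum(trz$edge.length), 0, tolerance = 1e-9)
})
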