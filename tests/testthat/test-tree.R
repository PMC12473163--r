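pair_aln <- function(n, nti, ntv) {
  # two sequences of length n differing by exactly nti transitions and ntv
  # transversions (A->G and A->C on an all-A background)
  a <- rep("A", n)
  b <- rep("A", n)
  if (nti > 0) b[seq_len(nti)] <- "G"
  if (ntv > 0) b[nti + seq_len(ntv)] <- "C"
  locus_alignment(rbind(s1 = a, s2 = b), "pair")
}

test_that("identical sequences have zero distance under both models", {
  aln <- locus_alignment(c(a = strrep("ACGT", 25), b = strrep("ACGT", 25)))
  expect_equal(unname(pairwise_distance(aln, "p")["a", "b"]), 0)
  expect_equal(unname(pairwise_distance(aln, "K2P")["a", "b"]), 0)
})

test_that("K2P matches the closed form on a grid of (P, Q)", {
  n <- 200L
  for (nti in c(0L, 4L, 10L, 20L, 40L)) {
    for (ntv in c(0L, 2L, 10L, 30L)) {
      aln <- pair_aln(n, nti, ntv)
      P <- nti / n; Q <- ntv / n
      got <- unname(pairwise_distance(aln, "K2P")["s1", "s2"])
      want <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # spot value from direct numeric evaluation: P=0.1, Q=0.05
  expect_equal(unname(pairwise_distance(pair_aln(200, 20, 10),
                                        "K2P")["s1", "s2"]),
               0.17017, tolerance = 1e-4)
})

test_that("K2P agrees with an established implementation", {
  withr::local_seed(2)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 300, replace = TRUE), 5,
              dimnames = list(paste0("t", 1:5), NULL))
  base <- m[1, ]
  for (i in 2:5) {
    keep <- runif(300) > 0.12
    m[i, !keep] <- sample(c("A", "C", "G", "T"), sum(!keep), replace = TRUE)
    m[i, keep] <- base[keep]
  }
  aln <- locus_alignment(m, "x")
  mine <- pairwise_distance(aln, "K2P")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10)
})

test_that("saturated pairs are flagged undefined, and NJ refuses them", {
  aln <- pair_aln(100, 50, 0)  # P = 0.5 -> log domain violated
  d <- pairwise_distance(aln, "K2P")
  expect_true(is.infinite(d["s1", "s2"]))
  d3 <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), "a/c")
})

test_that("K2P dominates the p-distance wherever defined", {
  withr::local_seed(14)
  for (rep in 1:20) {
    aln <- rand_alignment(ntaxa = 6, ncols = 120, mut_prob = 0.15)
    dp <- pairwise_distance(aln, "p")
    dk <- pairwise_distance(aln, "K2P")
    ok <- is.finite(dk) & !is.nan(dp)
    expect_true(all(dk[ok] >= dp[ok] - 1e-12))
    expect_true(all((dk == 0) == (dp == 0), na.rm = TRUE))
  }
})

test_that("NJ recovers additive quartets and random additive topologies", {
  # hand-built additive matrix for ((a,b),(c,d))
  d <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(tree_splits(tr), paste(sort(c("c", "d")), collapse = "|"))
  withr::local_seed(77)
  for (rep in 1:30) {
    inst <- rand_additive()
    nj <- neighbor_joining(inst$d)
    expect_equal(rf_distance(nj, inst$tree), 0L)
    # cross-check against an independent NJ implementation
    ref <- ape::nj(as.dist(inst$d))
    expect_equal(rf_distance(nj, ref), 0L)
  }
})

test_that("NJ edge cases: determinism on ties, rooting, clamping", {
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  t1 <- neighbor_joining(d3)
  t2 <- neighbor_joining(d3)
  expect_equal(write_newick(t1), write_newick(t2))
  expect_true(all(t1$edge.length >= 0))
  d <- matrix(c(0, 2, 7, 7, 2, 0, 7, 7, 7, 7, 0, 2, 7, 7, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  rooted <- neighbor_joining(d, outgroup = "d")
  expect_true(ape::is.rooted(rooted))
  expect_error(neighbor_joining(d, outgroup = "zz"), "outgroup")
  # negative branch estimates are clamped to zero, deficit moved to sister
  dn <- matrix(c(0, 5, 9, 10,
                 5, 0, 10, 9,
                 9, 10, 0, 8,
                 10, 9, 8, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  trn <- neighbor_joining(dn)
  expect_true(all(trn$edge.length >= 0))
})

test_that("Robinson-Foulds distance counts asymmetric bipartitions", {
  t1 <- read_newick("((a,b),(c,d));")
  t2 <- read_newick("((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  star <- read_newick("(a,b,c,d,e);")
  resolved <- read_newick("((a,b),(c,d),e);")
  # equals the number of internal edges of the resolved tree
  expect_equal(rf_distance(star, resolved), 2L)
  expect_error(rf_distance(t1, read_newick("((a,b),(c,e));")),
               "leaf sets")
  skip_if_not_installed("phangorn")
  withr::local_seed(23)
  for (rep in 1:10) {
    ta <- ape::rtree(7); tb <- ape::rtree(7)
    expect_equal(rf_distance(ta, tb),
                 as.integer(phangorn::RF.dist(ape::unroot(ta),
                                              ape::unroot(tb))))
  }
})

test_that("bootstrap support is deterministic per seed and bounded", {
  withr::local_seed(55)
  ps <- planted_split_alignment(n_per_clade = 4, ncols = 300, k = 25,
                                noise_prob = 0.01)
  sm <- concatenate_loci(list(ps$aln))
  b1 <- bootstrap_support(sm, n_reps = 20, seed = 9)
  b2 <- bootstrap_support(sm, n_reps = 20, seed = 9)
  expect_equal(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  b_one <- bootstrap_support(sm, n_reps = 1, seed = 3)
  expect_true(all(b_one$support %in% c(0, 100)))
})

test_that("a heavily supported planted split earns high bootstrap support", {
  withr::local_seed(66)
  ps <- planted_split_alignment(n_per_clade = 5, ncols = 1000, k = 50,
                                noise_prob = 0.005)
  sm <- concatenate_loci(list(ps$aln))
  boot <- bootstrap_support(sm, n_reps = 100, seed = 12)
  expect_gte(clade_support(boot, ps$ingroup), 95)
})
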