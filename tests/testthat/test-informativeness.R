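test_that("shared identical gap runs collapse into one indel event", {
  aln <- locus_alignment(c(r1 = "AC--GT", r2 = "ACTTGT", r3 = "AC--GT"))
  ev <- find_indels(aln)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end, ev$length), c(2L, 4L, 2L))
  expect_equal(ev$carriers, "r1,r3")
  expect_equal(ev$n_carriers, 2L)
})

test_that("gap runs at different columns are separate events", {
  aln <- locus_alignment(c(r1 = "A-CGT", r2 = "AC-GT"))
  ev <- find_indels(aln)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$length, c(1L, 1L))
  expect_equal(ev$start, c(1L, 2L))
})

test_that("terminal gap runs are excluded unless requested", {
  aln <- locus_alignment(c(r1 = "--CGTAA", r2 = "ACCGT--", r3 = "ACCGTAA"))
  expect_equal(nrow(find_indels(aln)), 0L)
  ev <- find_indels(aln, include_terminal = TRUE)
  expect_equal(nrow(ev), 2L)
  aln2 <- locus_alignment(c(r1 = "ACGTACGT", r2 = "ACGTACGT"))
  expect_equal(nrow(find_indels(aln2)), 0L)
})

test_that("consensus substitution counting follows the tie and class rules", {
  # A,A,G,G: alphabetical tie -> consensus A, one transition
  aln <- locus_alignment(c(r1 = "A", r2 = "A", r3 = "G", r4 = "G"))
  expect_equal(unname(count_substitutions(aln)), c(1L, 0L))
  # A,C,G: consensus A; C is a transversion, G a transition
  aln2 <- locus_alignment(c(r1 = "A", r2 = "C", r3 = "G"))
  expect_equal(unname(count_substitutions(aln2)), c(1L, 1L))
  # invariant column
  aln3 <- locus_alignment(c(r1 = "T", r2 = "T", r3 = "T"))
  expect_equal(unname(count_substitutions(aln3)), c(0L, 0L))
  # gaps and ambiguity codes are ignored
  aln4 <- locus_alignment(c(r1 = "A?", r2 = "GC", r3 = "GC", r4 = "GA"))
  expect_equal(unname(count_substitutions(aln4)), c(1L, 1L))
  # a column left with a single non-missing state contributes nothing
  aln5 <- locus_alignment(c(r1 = "-", r2 = "N", r3 = "C", r4 = "C"))
  expect_equal(unname(count_substitutions(aln5)), c(0L, 0L))
})

test_that("SSR detection: canonical motifs, thresholds, primitivity", {
  hit <- find_ssr("ATATATATATATAT")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "AT")
  expect_equal(hit$repeats, 7L)
  expect_equal(hit$length, 14L)
  expect_equal(nrow(find_ssr("ATATAT")), 0L)       # 3 repeats < 6
  mono <- find_ssr("AAAAAAAAAA")
  expect_equal(c(mono$motif, mono$repeats), c("A", "10"))
  expect_equal(nrow(find_ssr("AAAAAAAAA")), 0L)    # 9 < 10
  # motif reported in canonical rotation
  rot <- find_ssr(paste0("CC", strrep("GA", 7), "CC"))
  expect_equal(rot$motif, "AG")
  # N breaks arrays
  expect_equal(nrow(find_ssr(paste0("AAAAA", "N", "AAAAA"))), 0L)
})

test_that("SSR oracle equivalence on planted and random sequences", {
  withr::local_seed(31)
  for (rep in 1:40) {
    parts <- c(
      paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
            collapse = ""),
      strrep(sample(c("A", "T", "AT", "AG", "CAT"), 1), sample(2:12, 1)),
      paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
            collapse = ""))
    s <- paste(parts, collapse = "")
    expect_equal(find_ssr(s), brute_ssr(s), info = s)
  }
})

test_that("SSR loci merge across rows by motif and overlap", {
  arr <- strrep("AT", 7)
  pad1 <- "GCGCGC"; pad2 <- "CGCGCG"
  aln <- locus_alignment(c(r1 = paste0(pad1, arr, pad2),
                           r2 = paste0(pad1, arr, pad2)))
  res <- count_ssr_loci(aln)
  expect_equal(res$count, 1L)
  # different motifs at different positions stay separate
  a2 <- paste0(strrep("AG", 6), "CCCGGC", strrep("AT", 7))
  b2 <- paste0("CCGCAATCGGCA", "GGCCCG", strrep("AT", 7))
  aln2 <- locus_alignment(c(r1 = a2, r2 = b2))
  expect_equal(count_ssr_loci(aln2)$count, 2L)
  # gapped rows map through alignment coordinates before merging
  aln3 <- locus_alignment(c(r1 = paste0("--", arr, "GCGCGC"),
                            r2 = paste0("CC", arr, "GCGCGC")))
  expect_equal(count_ssr_loci(aln3)$count, 1L)
  # SSR-free alignment
  aln4 <- locus_alignment(c(r1 = "ACGTGCA", r2 = "ACGTGCA"))
  expect_equal(count_ssr_loci(aln4)$count, 0L)
})

test_that("parsimony-informative sites follow the two-by-two rule", {
  aln <- locus_alignment(c(r1 = "ACGT", r2 = "ACGT", r3 = "GCGT",
                           r4 = "GCGA"))
  res <- count_pis(aln)
  expect_equal(res$count, 1L)
  expect_equal(res$sites, 0L)
  expect_equal(count_pis(locus_alignment(c(a = "AAA", b = "AAA")))$count, 0L)
  # singleton state backed by a gap is not informative
  aln2 <- locus_alignment(c(r1 = "A", r2 = "A", r3 = "G", r4 = "-"))
  expect_equal(count_pis(aln2)$count, 0L)
})

test_that("PIS, indel and SSR detectors agree with brute-force oracles", {
  withr::local_seed(99)
  for (rep in 1:60) {
    aln <- rand_alignment()
    expect_equal(count_pis(aln)$sites, brute_pis(aln))
    det <- find_indels(aln)
    bru <- brute_indels(aln)
    expect_equal(det[, c("start", "end", "carriers")],
                 bru[, c("start", "end", "carriers")],
                 ignore_attr = TRUE)
    det_t <- find_indels(aln, include_terminal = TRUE)
    bru_t <- brute_indels(aln, include_terminal = TRUE)
    expect_equal(nrow(det_t), nrow(bru_t))
  }
  for (rep in 1:20) {
    aln <- rand_ssr_alignment()
    for (tx in sample(aln_taxa(aln), 2)) {
      s <- aln_strings(aln, degap = TRUE)[[tx]]
      expect_equal(find_ssr(s), brute_ssr(s))
    }
  }
})

test_that("counts are invariant under row permutation", {
  withr::local_seed(7)
  aln <- rand_alignment(ntaxa = 8, ncols = 80)
  perm <- sample(nrow(aln$matrix))
  aln_p <- locus_alignment(aln$matrix[perm, , drop = FALSE], aln$locus_name)
  expect_equal(count_pis(aln_p)$sites, count_pis(aln)$sites)
  expect_equal(count_substitutions(aln_p), count_substitutions(aln))
  expect_equal(count_ssr_loci(aln_p)$count, count_ssr_loci(aln)$count)
  a <- find_indels(aln); b <- find_indels(aln_p)
  expect_equal(a[, c("start", "end", "carriers")],
               b[, c("start", "end", "carriers")])
})

test_that("adding an invariant gap-free row never lowers informativeness", {
  withr::local_seed(21)
  for (rep in 1:10) {
    aln <- rand_alignment(ntaxa = 6, ncols = 60)
    cons <- apply(aln$matrix, 2, function(col) {
      col <- col[col %in% c("A", "C", "G", "T")]
      if (length(col) == 0) "A" else {
        tab <- table(col)
        names(tab)[which.max(tab)]
      }
    })
    m2 <- rbind(aln$matrix, extra = cons)
    aln2 <- locus_alignment(m2, aln$locus_name)
    expect_equal(find_indels(aln2)[, c("start", "end")],
                 find_indels(aln)[, c("start", "end")])
    expect_equal(count_substitutions(aln2), count_substitutions(aln))
    expect_gte(count_pis(aln2)$count, count_pis(aln)$count)
  }
})

test_that("the assembled report matches hand-counted toy truth", {
  arr <- strrep("AT", 7)                     # one SSR locus
  r1 <- paste0("AAC", "GG", "TTTCAG", arr, "GTCAA")
  r2 <- paste0("AAC", "--", "TTTCAG", arr, "GTCAA")  # shared 2-bp indel
  r3 <- paste0("AAC", "--", "TTTCAG", arr, "GTCGA")  # + one transition (A->G)
  aln <- locus_alignment(c(r1 = r1, r2 = r2, r3 = r3), "toy")
  rep <- informativeness_report(aln)
  expect_equal(rep$n_indels, 1L)
  expect_equal(rep$indel_bp, 2L)
  expect_equal(rep$transitions, 1L)
  expect_equal(rep$transversions, 0L)
  expect_equal(rep$n_ssr, 1L)
  expect_equal(rep$length, nchar(r1))
})

test_that("a variation-free alignment reports zeros and its length", {
  flat <- "ACGGATTCAGCTAAGCTTGGCCAATCCGGAAGTCATGACT"  # no tandem arrays
  aln <- locus_alignment(c(a = flat, b = flat), "flat")
  rep <- informativeness_report(aln)
  expect_equal(rep$length, 40L)
  expect_equal(rep$n_indels + rep$indel_bp + rep$transitions +
                 rep$transversions + rep$n_ssr + rep$n_pis, 0L)
})
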