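test_that("spacer extraction returns the inter-gene interval", {
  g <- toy_genome()
  spec <- region_spec("geneA-geneB", "spacer",
                      flank_genes = c("geneA", "geneB"))
  s <- extract_region(g, spec)
  expect_equal(unclass(s)[[1]], substr(g$residues, 21, 30))
  expect_equal(nchar(unclass(s)[[1]]), 10L)
  expect_false(attr(s, "empty"))
})

test_that("extraction is strand-consistent under genome reverse complement", {
  g <- toy_genome()
  spec <- region_spec("geneA-geneB", "spacer",
                      flank_genes = c("geneA", "geneB"))
  n <- nchar(g$residues)
  f <- g$features
  rc <- genome_record("toyrc", revcomp(g$residues), data.frame(
    type = f$type, gene = f$gene, start = n - f$end, end = n - f$start,
    strand = ifelse(f$strand == "+", "-", "+"),
    feature_id = f$feature_id, part = f$part))
  s_fwd <- unclass(extract_region(g, spec))[[1]]
  s_rc <- unclass(extract_region(rc, spec))[[1]]
  # extraction is orientation-normalised (first-named flank upstream), so a
  # genome and its reverse complement deliver the identical spacer sequence
  expect_equal(s_rc, s_fwd)
})

test_that("missing flank genes and adjacent genes are handled as specified", {
  g <- toy_genome()
  expect_error(extract_region(g, region_spec("geneA-geneX", "spacer",
                                             flank_genes = c("geneA", "geneX"))),
               "not annotated")
  # overlapping/adjacent flanks give a flagged empty result, not an error
  feats <- data.frame(type = "gene", gene = c("g1", "g2"),
                      start = c(0L, 10L), end = c(10L, 20L),
                      strand = "+", feature_id = 1:2, part = 1L)
  g2 <- genome_record("adj", strrep("ACGT", 10), feats)
  s <- extract_region(g2, region_spec("g1-g2", "spacer",
                                      flank_genes = c("g1", "g2")))
  expect_true(attr(s, "empty"))
})

test_that("reversed gene order yields the reverse complement", {
  # geneB before geneA on the genome: 'A-B' spacer must be delivered with A
  # upstream, i.e. reverse-complemented relative to the plus strand
  feats <- data.frame(type = "gene", gene = c("geneB", "geneA"),
                      start = c(5L, 30L), end = c(10L, 35L),
                      strand = "-", feature_id = 1:2, part = 1L)
  res <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
  g <- genome_record("rev", res, feats)
  spec <- region_spec("geneA-geneB", "spacer",
                      flank_genes = c("geneA", "geneB"))
  s <- extract_region(g, spec)
  expect_equal(unclass(s)[[1]], revcomp(substr(res, 11, 30)))
})

test_that("multi-copy flank genes pick the nearest pair; ties error", {
  feats <- data.frame(
    type = "gene", gene = c("gA", "gB", "gA"),
    start = c(0L, 20L, 50L), end = c(10L, 30L, 60L),
    strand = "+", feature_id = 1:3, part = 1L)
  res <- strrep("ACGT", 20)
  g <- genome_record("ir", res, feats)
  s <- extract_region(g, region_spec("gA-gB", "spacer",
                                     flank_genes = c("gA", "gB")))
  expect_equal(unclass(s)[[1]], substr(res, 11, 20))  # nearest copy pair
  feats2 <- feats
  feats2$start <- c(0L, 20L, 40L); feats2$end <- c(10L, 30L, 50L)
  g2 <- genome_record("tie", res, feats2)
  expect_error(extract_region(g2, region_spec("gA-gB", "spacer",
                                              flank_genes = c("gA", "gB"))),
               "ambiguous")
})

test_that("same-gene spacers span the two nearest distinct copies", {
  g <- toy_genome()  # geneD has parts at [80,100) and [120,140)
  feats <- data.frame(type = "gene", gene = c("tK", "mK", "tK"),
                      start = c(0L, 20L, 60L), end = c(10L, 50L, 70L),
                      strand = "+", feature_id = 1:3, part = 1L)
  res <- strrep("GATC", 20)
  g <- genome_record("tk", res, feats)
  s <- extract_region(g, region_spec("tK-mK-tK", "spacer",
                                     flank_genes = c("tK", "tK")))
  expect_equal(unclass(s)[[1]], substr(res, 11, 60))
})

test_that("intron extraction takes inter-exon sequence in gene orientation", {
  res <- strrep("ACGTT", 40)  # 200 bp
  feats <- data.frame(type = "gene", gene = "host",
                      start = c(10L, 60L, 120L), end = c(30L, 90L, 150L),
                      strand = "+", feature_id = 1L, part = 1:3)
  g <- genome_record("intr", res, feats)
  i1 <- extract_region(g, region_spec("host intron 1", "intron",
                                      host_gene = "host",
                                      intron_ordinal = 1))
  i2 <- extract_region(g, region_spec("host intron 2", "intron",
                                      host_gene = "host",
                                      intron_ordinal = 2))
  expect_equal(unclass(i1)[[1]], substr(res, 31, 60))
  expect_equal(unclass(i2)[[1]], substr(res, 91, 120))
  # minus-strand host: ordinal 1 is the 3'-most interval, reverse-complemented
  feats$strand <- "-"
  gm <- genome_record("intrm", res, feats)
  i1m <- extract_region(gm, region_spec("host intron 1", "intron",
                                        host_gene = "host",
                                        intron_ordinal = 1))
  expect_equal(unclass(i1m)[[1]], revcomp(substr(res, 91, 120)))
  expect_error(extract_region(g, region_spec("host intron 3", "intron",
                                             host_gene = "host",
                                             intron_ordinal = 3)),
               "2 intron")
})

test_that("identical sequences align without gaps", {
  s <- dna_seqs(c(a = "ACGTACGTAA", b = "ACGTACGTAA", c = "ACGTACGTAA"))
  aln <- align_homologs(s)
  expect_equal(aln$length, 10L)
  expect_false(any(aln$matrix == "-"))
})

test_that("center-star alignment matches the affine DP oracle on a 1-gap pair", {
  s <- dna_seqs(c(a = "ACGTACGT", b = "ACGACGT"))
  aln <- align_homologs(s)
  rows <- aln_strings(aln)
  # residue content preserved
  expect_equal(gsub("-", "", rows[["b"]]), "ACGACGT")
  expect_equal(rows[["a"]], "ACGTACGT")
  expect_equal(sum(strsplit(rows[["b"]], "")[[1]] == "-"), 1L)
  # achieved score equals the DP optimum
  expect_equal(score_pairwise(rows[["a"]], rows[["b"]]),
               nw_affine_score("ACGTACGT", "ACGACGT"))
})

test_that("pairwise step attains the DP-optimal affine score on random pairs", {
  withr::local_seed(11)
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(6:20, 1), TRUE),
               collapse = "")
    aln <- align_homologs(dna_seqs(c(x = a, y = b)))
    rows <- aln_strings(aln)
    expect_equal(score_pairwise(rows[["x"]], rows[["y"]]),
                 nw_affine_score(a, b),
                 info = paste(a, b))
  }
})

test_that("degapping aligned rows always reproduces the inputs", {
  withr::local_seed(5)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
            collapse = ""), character(1))
    names(seqs) <- sprintf("s%d", seq_len(n))
    aln <- align_homologs(dna_seqs(seqs))
    expect_equal(aln_strings(aln, degap = TRUE)[names(seqs)], seqs)
  }
})

test_that("alignment input validation", {
  expect_error(align_homologs(dna_seqs(c(a = "ACGT"))), "at least 2")
  big <- dna_seqs(c(a = strrep("ACGT", 1300), b = strrep("ACGT", 1300)))
  expect_error(align_homologs(big), "5 kb")
})

test_that("screen_regions scores constructed spacers and flags partials", {
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  mk <- function(id, spacer) {
    res <- paste0(substr(base, 1, 10), spacer, substr(base, 31, 60))
    feats <- data.frame(type = "gene", gene = c("gL", "gR"),
                        start = c(0L, 10L + nchar(spacer)),
                        end = c(10L, 20L + nchar(spacer)),
                        strand = "+", feature_id = 1:2, part = 1L)
    genome_record(id, res, feats)
  }
  sp0 <- "AAAACCCCGGGGTTTTAAAA"
  sp1 <- sp0; substr(sp1, 3, 3) <- "G"   # one transition (A->G)
  sp2 <- sp0; substr(sp2, 7, 7) <- "T"   # one transition (C->T)
  genomes <- list(mk("g1", sp0), mk("g2", sp1), mk("g3", sp2))
  cat2 <- structure(list(
    `gL-gR` = region_spec("gL-gR", "spacer", flank_genes = c("gL", "gR")),
    `gL-gX` = region_spec("gL-gX", "spacer", flank_genes = c("gL", "gX"))),
    class = "region_catalogue")
  out <- screen_regions(genomes, cat2)
  expect_equal(nrow(out$report), 1L)
  expect_equal(out$report$transitions, 2L)
  expect_equal(out$report$transversions, 0L)
  expect_true(any(grepl("gL-gX", out$log)))

  # region available in only two of three genomes -> partial but scored
  g3 <- genomes[[3]]
  g3$features <- g3$features[g3$features$gene != "gR", , drop = FALSE]
  g3 <- genome_record("g3b", g3$residues, g3$features)
  out2 <- screen_regions(list(genomes[[1]], genomes[[2]], g3),
                         structure(cat2["gL-gR"],
                                   class = "region_catalogue"))
  expect_true(out2$report$partial)
  expect_equal(out2$report$transitions, 1L)
})

test_that("identical genomes screen to all-zero scores", {
  g <- toy_genome()
  cat1 <- structure(list(
    `geneA-geneB` = region_spec("geneA-geneB", "spacer",
                                flank_genes = c("geneA", "geneB"))),
    class = "region_catalogue")
  g2 <- genome_record("toy2", g$residues, g$features)
  out <- screen_regions(list(g, g2), cat1)
  expect_equal(out$report$transitions + out$report$transversions, 0L)
  expect_equal(out$report$n_indels, 0L)
})
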