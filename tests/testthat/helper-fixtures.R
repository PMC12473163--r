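# Programmatic fixtures: random alignments with controlled features, toy
# annotated genomes, GenBank flat-file text, random additive distances.

rand_alignment <- function(ntaxa = NULL, ncols = NULL, gap_runs = 2,
                           shared_gap_prob = 0.5, mut_prob = 0.1,
                           ambig_prob = 0.01) {
  if (is.null(ntaxa)) ntaxa <- sample(4:20, 1)
  if (is.null(ncols)) ncols <- sample(30:200, 1)
  anc <- sample(c("A", "C", "G", "T"), ncols, replace = TRUE)
  m <- matrix(rep(anc, each = ntaxa), nrow = ntaxa)
  rownames(m) <- sprintf("t%02d", seq_len(ntaxa))
  mut <- matrix(runif(ntaxa * ncols) < mut_prob, ntaxa, ncols)
  m[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
  amb <- matrix(runif(ntaxa * ncols) < ambig_prob, ntaxa, ncols)
  m[amb] <- sample(c("N", "R", "Y", "W"), sum(amb), replace = TRUE)
  for (k in seq_len(gap_runs)) {
    len <- sample(1:5, 1)
    start <- sample(seq_len(max(1, ncols - len)), 1)
    if (runif(1) < shared_gap_prob) {
      rows <- sample(ntaxa, sample(1:max(1, ntaxa %/% 2), 1))
    } else {
      rows <- sample(ntaxa, 1)
    }
    m[rows, start:(start + len - 1)] <- "-"
  }
  locus_alignment(m, locus_name = "rand")
}

# alignment enriched with planted tandem arrays for SSR oracle checks
rand_ssr_alignment <- function(ntaxa = 6, ncols = 150) {
  aln <- rand_alignment(ntaxa, ncols, gap_runs = 1, mut_prob = 0.05,
                        ambig_prob = 0.005)
  m <- aln$matrix
  for (r in sample(ntaxa, sample(2:ntaxa, 1))) {
    motif <- sample(c("A", "T", "AT", "AG", "CTT"), 1)
    reps <- sample(3:12, 1)
    arr <- strsplit(strrep(motif, reps), "")[[1]]
    if (length(arr) >= ncols - 2) next
    start <- sample(seq_len(ncols - length(arr)), 1)
    m[r, start:(start + length(arr) - 1)] <- arr
  }
  locus_alignment(m, locus_name = "ssr_rand")
}

# toy annotated genome: geneA [10,20)+ , geneB [30,40)+ , geneC [55,65)-,
# plus a two-exon gene with an intron, on a 120 bp sequence
toy_genome <- function(id = "toy1", seed = 1) {
  withr::with_seed(seed, {
    res <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
                 collapse = "")
  })
  feats <- data.frame(
    type = c("gene", "gene", "gene", "gene", "gene"),
    gene = c("geneA", "geneB", "geneC", "geneD", "geneD"),
    start = c(10L, 30L, 55L, 80L, 120L),
    end = c(20L, 40L, 65L, 100L, 140L),
    strand = c("+", "+", "-", "+", "+"),
    feature_id = c(1L, 2L, 3L, 4L, 4L),
    part = c(1L, 1L, 1L, 1L, 2L))
  genome_record(id, res, feats)
}

genbank_text <- function(id = "SYN001", seq = NULL, features = NULL) {
  if (is.null(seq)) {
    seq <- paste(rep("ACGT", 25), collapse = "")  # 100 bp
  }
  if (is.null(features)) {
    features <- c(
      "     gene            11..20",
      "                     /gene=\"geneA\"",
      "     gene            complement(31..40)",
      "                     /gene=\"geneB\"")
  }
  body <- tolower(seq)
  chunks <- substring(body, seq(1, nchar(body), 60),
                      pmin(seq(1, nchar(body), 60) + 59, nchar(body)))
  origin <- sprintf("%9d %s", seq(1, nchar(body), 60), chunks)
  c(sprintf("LOCUS       %s             %d bp    DNA     circular PLN", id,
            nchar(seq)),
    sprintf("ACCESSION   %s", id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    features,
    "ORIGIN",
    origin,
    "//")
}

write_genbank_fixture <- function(path, ...) {
  writeLines(genbank_text(...), path)
  path
}

# random additive distance matrix + the generating topology
rand_additive <- function(ntaxa = NULL) {
  if (is.null(ntaxa)) ntaxa <- sample(4:8, 1)
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 1))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# two-clade alignment with k planted fixed differences and optional noise
planted_split_alignment <- function(n_per_clade = 5, ncols = 1000, k = 20,
                                    noise_prob = 0) {
  taxa <- c(sprintf("in%02d", seq_len(n_per_clade)),
            sprintf("out%02d", seq_len(n_per_clade)))
  anc <- sample(c("A", "C", "G", "T"), ncols, replace = TRUE)
  m <- matrix(rep(anc, each = 2 * n_per_clade), nrow = 2 * n_per_clade)
  rownames(m) <- taxa
  diff_cols <- sample(ncols, k)
  for (j in diff_cols) {
    alt <- setdiff(c("A", "C", "G", "T"), anc[j])[sample(3, 1)]
    m[seq_len(n_per_clade), j] <- alt
  }
  if (noise_prob > 0) {
    noise <- matrix(runif(nrow(m) * ncols) < noise_prob, nrow(m), ncols)
    noise[, diff_cols] <- FALSE
    m[noise] <- sample(c("A", "C", "G", "T"), sum(noise), replace = TRUE)
  }
  list(aln = locus_alignment(m, "planted"),
       ingroup = sprintf("in%02d", seq_len(n_per_clade)),
       diff_cols = sort(diff_cols - 1L))
}
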