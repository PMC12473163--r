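# The default study regime for the simulator: sixteen taxa in two diverged
# clades plus a distant outgroup, and nine loci (seven plastid spacers, two
# nuclear ribosomal markers) whose aligned lengths and per-locus event
# targets match a published marker-informativeness survey regime: loci of
# 400-1100 bp carrying tens of substitutions, 10-22 indel events and 8-41
# microsatellite loci each. These values are the generator's study
# conditions, not tuning knobs.

#' Per-locus targets of the default marker-survey regime
#'
#' @return data.frame with `locus`, `length` (aligned bp), `n_indels`,
#'   `indel_bp`, `ti`, `tv`, `n_ssr` and `genome` ("plastid"/"nuclear").
#' @export
marker_regime <- function() {
  data.frame(
    locus = c("trnS-psbK", "trnL-rpl32", "rps16-trnQ", "rps16-trnK",
              "rps15-ycf1", "psbA-trnH", "petN-psbM", "ITS", "ETS"),
    length = c(703L, 903L, 1002L, 710L, 611L, 424L, 1057L, 702L, 408L),
    n_indels = c(21L, 16L, 22L, 15L, 12L, 10L, 19L, 15L, 16L),
    indel_bp = c(90L, 91L, 206L, 67L, 144L, 61L, 47L, 21L, 24L),
    ti = c(11L, 27L, 21L, 19L, 24L, 13L, 21L, 77L, 138L),
    tv = c(19L, 34L, 31L, 23L, 12L, 21L, 17L, 47L, 68L),
    n_ssr = c(13L, 34L, 41L, 18L, 19L, 13L, 25L, 17L, 8L),
    genome = c(rep("plastid", 7), "nuclear", "nuclear"),
    stringsAsFactors = FALSE)
}

#' The default two-clade study tree
#'
#' Sixteen taxa: a seven-taxon clade (six perennial cushion-mint taxa plus
#' their annual relative), an eight-taxon sister clade, and one distant
#' outgroup on a long branch. Branch lengths are relative units scaled by
#' the per-locus substitution rates.
#'
#' @return a rooted "phylo" tree.
#' @export
marker_tree <- function() {
  txt <- paste0(
    "(micromeria_croatica:0.06,(",
    "(((ac_acinos:0.02,ac_alpinum:0.02):0.01,",
    "(ac_albanicum:0.02,ac_hungaricum:0.02):0.01):0.01,",
    "(ac_majoranifolium:0.02,(ac_suaveolens:0.02,",
    "ziziphora_capitata:0.03):0.01):0.01):0.04,",
    "(((ca_menthifolium:0.02,ca_vardarense:0.02):0.01,",
    "(ca_nepeta:0.02,ca_spruneri:0.02):0.01):0.01,",
    "((ps_album:0.02,(ps_pulegium:0.02,ps_dalmaticum:0.02):0.01):0.01,",
    "clinopodium_vulgare:0.03):0.01):0.04):0.02);")
  ape::read.tree(text = txt)
}

#' Ingroup of the focal clade split in the default regime
#'
#' @return a [clade_partition] for the annual (Acinos/Ziziphora-type) clade.
#' @export
focal_partition <- function() {
  clade_partition("acinos_ziziphora",
                  c("ac_acinos", "ac_alpinum", "ac_albanicum",
                    "ac_hungaricum", "ac_majoranifolium", "ac_suaveolens",
                    "ziziphora_capitata"))
}

.ssr_seed_table <- function(n) {
  motifs <- rep(c("A", "AT", "T", "TA"), length.out = n)
  data.frame(motif = motifs,
             repeats = ifelse(nchar(motifs) == 1, 11L, 7L),
             step_rate = 0.3, expand_prob = 0,
             stringsAsFactors = FALSE)
}

#' Simulation configuration for the default marker-survey regime
#'
#' Per-locus substitution and indel rates are back-calculated so that the
#' expected event counts over the whole tree equal the regime targets:
#' rate = target / (length * total tree length). The transition bias kappa
#' is set from the target transition:transversion ratio (kappa = 2 ti/tv).
#' Indels are deletions only and microsatellite steps are contractions only,
#' which pins the aligned length of every locus to its configured value
#' (insertions would add alignment columns).
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
marker_regime_config <- function(seed = 1) {
  tree <- marker_tree()
  regime <- marker_regime()
  T <- sum(tree$edge.length)
  loci <- lapply(seq_len(nrow(regime)), function(i) {
    r <- regime[i, ]
    sim_locus(
      name = r$locus, length = r$length,
      sub_rate = (r$ti + r$tv) / (r$length * T),
      kappa = 2 * r$ti / r$tv,
      indel_rate = r$n_indels / (r$length * T),
      indel_mean = r$indel_bp / r$n_indels,
      ins_prob = 0,
      ssr = .ssr_seed_table(r$n_ssr))
  })
  sim_config(tree, loci, seed = seed)
}

#' Generate the default marker-survey fixture set
#'
#' Simulates the nine-locus regime and returns the alignments, ground truth
#' and the per-locus targets.
#'
#' @param seed integer seed.
#' @return a `sim_result` with extra elements `regime` (the target table)
#'   and `partition` (the focal clade split).
#' @export
make_marker_fixture <- function(seed = 1) {
  sim <- simulate_loci(marker_regime_config(seed))
  sim$regime <- marker_regime()
  sim$partition <- focal_partition()
  sim
}

#' Synthetic annotated plastome-like records for screen demonstrations
#'
#' Builds `n` small annotated genome records (about 7 kb) that share a gene
#' order covering a subset of the built-in region catalogue: several
#' intergenic spacers, a duplicated tRNA gene pair enclosing a maturase
#' (the two-copy spacer case), and two intron-bearing genes. Gene sequences
#' are conserved; spacer and intron sequences diverge between records by
#' substitutions and occasional short deletions. These are synthetic
#' stand-ins for annotated plastome accessions, not real sequences.
#'
#' @param n number of records (>= 2).
#' @param seed integer seed.
#' @param spacer_sub_prob per-site substitution probability applied to each
#'   non-gene segment of each record after the first.
#' @return list of [genome_record] objects.
#' @export
synthetic_plastomes <- function(n = 3, seed = 1, spacer_sub_prob = 0.05) {
  stopifnot(n >= 2)
  set.seed(seed)
  rand_seq <- function(len) paste(sample(DNA_STATES, len, replace = TRUE),
                                  collapse = "")
  # plan: alternating conserved gene segments and divergent spacer segments;
  # multi-part genes model introns, duplicated trnK models the two-copy case
  plan <- list(
    list(kind = "gene", gene = "psbA", len = 300, strand = "+"),
    list(kind = "spacer", len = 250),
    list(kind = "gene", gene = "trnH-GUG", len = 70, strand = "-"),
    list(kind = "spacer", len = 150),
    list(kind = "gene", gene = "petN", len = 90, strand = "+"),
    list(kind = "spacer", len = 300),
    list(kind = "gene", gene = "psbM", len = 100, strand = "+"),
    list(kind = "spacer", len = 200),
    list(kind = "gene", gene = "rps16", len = 250, strand = "+"),
    list(kind = "spacer", len = 350),
    list(kind = "gene", gene = "trnQ-UUG", len = 72, strand = "-"),
    list(kind = "spacer", len = 180),
    list(kind = "gene", gene = "psbK", len = 180, strand = "+"),
    list(kind = "spacer", len = 220),
    list(kind = "gene", gene = "trnS-UGA", len = 88, strand = "-"),
    list(kind = "spacer", len = 120),
    list(kind = "gene", gene = "rpl32", len = 160, strand = "+"),
    list(kind = "spacer", len = 280),
    list(kind = "gene", gene = "trnL-UAG", len = 80, strand = "-"),
    list(kind = "spacer", len = 100),
    list(kind = "gene", gene = "rps15", len = 270, strand = "+"),
    list(kind = "spacer", len = 320),
    list(kind = "gene", gene = "ycf1", len = 400, strand = "+"),
    list(kind = "spacer", len = 90),
    list(kind = "gene", gene = "trnK-UUU", len = 35, strand = "-"),
    list(kind = "spacer", len = 80),
    list(kind = "gene", gene = "matK", len = 400, strand = "-"),
    list(kind = "spacer", len = 70),
    list(kind = "gene", gene = "trnK-UUU", len = 37, strand = "-"),
    list(kind = "spacer", len = 150),
    list(kind = "gene", gene = "rpoC1", len = c(200, 300), strand = "+",
         intron_lens = 240),
    list(kind = "spacer", len = 130),
    list(kind = "gene", gene = "clpP", len = c(70, 60, 50), strand = "+",
         intron_lens = c(200, 180)),
    list(kind = "spacer", len = 100))
  # draw the shared base sequence per segment (gene parts + introns)
  base <- lapply(plan, function(seg) {
    if (seg$kind == "gene") {
      list(parts = vapply(seg$len, rand_seq, character(1)),
           introns = if (is.null(seg$intron_lens)) character(0) else
             vapply(seg$intron_lens, rand_seq, character(1)))
    } else {
      rand_seq(seg$len)
    }
  })
  mutate <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < p)
    ch[hit] <- sample(DNA_STATES, length(hit), replace = TRUE)
    if (stats::runif(1) < 0.3 && length(ch) > 20) {
      start <- sample.int(length(ch) - 10, 1)
      ch <- ch[-(start:(start + sample.int(6, 1) + 1))]
    }
    paste(ch, collapse = "")
  }
  out <- vector("list", n)
  for (g in seq_len(n)) {
    residues <- character(0)
    pos <- 0L
    feats <- list()
    fid <- 0L
    for (si in seq_along(plan)) {
      seg <- plan[[si]]
      if (seg$kind == "spacer") {
        s <- if (g == 1) base[[si]] else mutate(base[[si]], spacer_sub_prob)
        residues <- c(residues, s)
        pos <- pos + nchar(s)
      } else {
        fid <- fid + 1L
        starts <- integer(0); ends <- integer(0)
        for (k in seq_along(base[[si]]$parts)) {
          starts <- c(starts, pos)
          residues <- c(residues, base[[si]]$parts[k])
          pos <- pos + nchar(base[[si]]$parts[k])
          ends <- c(ends, pos)
          if (k <= length(base[[si]]$introns)) {
            intr <- if (g == 1) base[[si]]$introns[k] else
              mutate(base[[si]]$introns[k], spacer_sub_prob)
            residues <- c(residues, intr)
            pos <- pos + nchar(intr)
          }
        }
        feats[[length(feats) + 1]] <- data.frame(
          type = if (grepl("^trn", seg$gene)) "tRNA" else "gene",
          gene = seg$gene, start = starts, end = ends, strand = seg$strand,
          feature_id = fid, part = seq_along(starts),
          stringsAsFactors = FALSE)
      }
    }
    out[[g]] <- genome_record(sprintf("SYNPT%02d", g),
                              paste(residues, collapse = ""),
                              do.call(rbind, feats))
  }
  out
}
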