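# In-silico region harvesting: pull named intergenic spacers and introns out
# of annotated genome records, align homologous copies across records, and
# feed the alignments to the informativeness statistics.

.substr0 <- function(x, start, end) {
  # 0-based half-open extraction
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

.gene_features <- function(genome, gene) {
  f <- genome$features
  f <- f[f$type %in% c("gene", "tRNA", "rRNA", "CDS") &
           norm_gene_name(f$gene) == norm_gene_name(gene), , drop = FALSE]
  f
}

# span of each annotated copy (a copy = one feature_id), as [start,end)
.gene_copies <- function(genome, gene) {
  f <- .gene_features(genome, gene)
  if (nrow(f) == 0) return(NULL)
  # prefer 'gene' features; fall back to tRNA/rRNA/CDS if no gene entry
  if (any(f$type == "gene")) f <- f[f$type == "gene", , drop = FALSE]
  sp <- do.call(rbind, lapply(split(f, f$feature_id), function(p) {
    data.frame(feature_id = p$feature_id[1], start = min(p$start),
               end = max(p$end), strand = p$strand[1])
  }))
  sp[order(sp$start), , drop = FALSE]
}

#' Extract a catalogued region from an annotated genome
#'
#' For a spacer, returns the sequence between the two nearest annotated
#' copies of the flank genes; the result is reverse-complemented when the
#' second-named gene precedes the first on the '+' strand, so the first-named
#' gene is always upstream. For an intron, returns the sequence between
#' consecutive exon parts of the host gene (in the gene's own 5'->3'
#' orientation). When a gene is annotated multiple times (inverted-repeat
#' copies), the pair of copies minimising the spacer length is used; an exact
#' tie is an error demanding disambiguation. Flank genes that overlap or abut
#' yield a zero-length result flagged via the `"empty"` attribute, not an
#' error.
#'
#' @param genome a [genome_record].
#' @param spec a [region_spec].
#' @return a single-element [dna_seqs] named after the genome, with
#'   attributes `region` (the spec name) and `empty` (logical).
#' @export
extract_region <- function(genome, spec) {
  if (spec$kind == "spacer") {
    a <- spec$flank_genes[1]; b <- spec$flank_genes[2]
    same_gene <- norm_gene_name(a) == norm_gene_name(b)
    ca <- .gene_copies(genome, a)
    cb <- .gene_copies(genome, b)
    if (is.null(ca)) stop(sprintf("gene not annotated in %s: %s", genome$id, a),
                          call. = FALSE)
    if (is.null(cb)) stop(sprintf("gene not annotated in %s: %s", genome$id, b),
                          call. = FALSE)
    if (same_gene && nrow(ca) < 2) {
      stop(sprintf("gene %s annotated once in %s; need two copies", a,
                   genome$id), call. = FALSE)
    }
    # candidate pairs: every copy of A against every copy of B (distinct
    # features when A == B); gap = interval between the two spans
    cand <- expand.grid(i = seq_len(nrow(ca)), j = seq_len(nrow(cb)))
    if (same_gene) cand <- cand[ca$feature_id[cand$i] !=
                                  cb$feature_id[cand$j], , drop = FALSE]
    gaps <- apply(cand, 1, function(k) {
      s1 <- ca[k["i"], ]; s2 <- cb[k["j"], ]
      if (s1$end <= s2$start) s2$start - s1$end
      else if (s2$end <= s1$start) s1$start - s2$end
      else 0L  # overlapping annotations -> empty spacer
    })
    best <- min(gaps)
    hits <- which(gaps == best)
    if (length(hits) > 1 && !same_gene) {
      stop(sprintf("ambiguous flank-gene copies for %s in %s: %d equally near pairs; pin coordinates to disambiguate",
                   spec$name, genome$id, length(hits)), call. = FALSE)
    }
    if (same_gene && length(hits) > 1) {
      # both orderings of the same copy pair tie; take genomic order
      fwd <- vapply(hits, function(h)
        ca$start[cand$i[h]] <= cb$start[cand$j[h]], logical(1))
      hits <- hits[order(!fwd)]
    }
    k <- cand[hits[1], ]
    s1 <- ca[k$i, ]; s2 <- cb[k$j, ]
    if (s1$end <= s2$start) {
      seq <- .substr0(genome$residues, s1$end, s2$start)
    } else if (s2$end <= s1$start) {
      seq <- revcomp(.substr0(genome$residues, s2$end, s1$start))
    } else {
      seq <- ""
    }
  } else {
    parts <- .gene_features(genome, spec$host_gene)
    parts <- parts[parts$type %in% c("gene", "tRNA", "CDS"), , drop = FALSE]
    # need a multi-part (join) feature: pick the feature_id with most parts
    byid <- split(parts, parts$feature_id)
    nparts <- vapply(byid, nrow, integer(1))
    if (length(byid) == 0 || max(nparts) < 2) {
      stop(sprintf("gene not annotated with exon parts in %s: %s", genome$id,
                   spec$host_gene), call. = FALSE)
    }
    f <- byid[[which.max(nparts)]]
    f <- f[order(f$start), , drop = FALSE]
    k <- spec$intron_ordinal
    n_introns <- nrow(f) - 1L
    if (k > n_introns) {
      stop(sprintf("%s has %d intron(s) in %s; ordinal %d requested",
                   spec$host_gene, n_introns, genome$id, k), call. = FALSE)
    }
    # ordinal counts from the gene's 5' end
    idx <- if (f$strand[1] == "-") n_introns - k + 1L else k
    seq <- .substr0(genome$residues, f$end[idx], f$start[idx + 1L])
    if (f$strand[1] == "-") seq <- revcomp(seq)
  }
  empty <- !nzchar(seq)
  out <- dna_seqs(if (empty) "N" else seq, ids = genome$id,
                  descriptions = spec$name)
  attr(out, "region") <- spec$name
  attr(out, "empty") <- empty
  out
}

# --- center-star multiple alignment -----------------------------------------

.pairwise_affine <- function(center, other, params) {
  alphabet <- c(DNA_STATES, IUPAC_AMBIG)
  sm <- matrix(params$mismatch, length(alphabet), length(alphabet),
               dimnames = list(alphabet, alphabet))
  diag(sm) <- params$match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(other), Biostrings::DNAString(center),
    substitutionMatrix = sm, gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend), type = "global")
  list(other = as.character(Biostrings::alignedPattern(pa)),
       center = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Default alignment scoring parameters
#'
#' Match +1, mismatch -1, affine gaps: -4 to open plus -1 per gapped
#' position. No claim is made that these reproduce any external aligner.
#'
#' @return a named list.
#' @export
align_params <- function() {
  list(match = 1, mismatch = -1, gap_open = -4, gap_extend = -1)
}

#' Align homologous sequences (center-star)
#'
#' Deterministic multiple alignment for screen-scale loci: every sequence is
#' globally aligned to a center sequence (the longest; ties broken by input
#' order) with affine gap penalties, and the pairwise alignments are merged
#' "once a gap, always a gap" around the center. Degapping any output row
#' reproduces the corresponding input exactly.
#'
#' @param seqs a [dna_seqs] with >= 2 sequences, each < 5 kb.
#' @param params scoring parameters, see [align_params()].
#' @param locus_name name for the resulting alignment.
#' @return a `locus_alignment`.
#' @export
align_homologs <- function(seqs, params = align_params(),
                           locus_name = "locus") {
  x <- unclass(seqs)
  if (length(x) < 2) stop("need at least 2 sequences to align", call. = FALSE)
  if (any(!nzchar(x))) stop("empty sequence in alignment input", call. = FALSE)
  if (any(nchar(x) >= 5000)) {
    stop("align_homologs is for screen-scale loci (< 5 kb)", call. = FALSE)
  }
  ids <- names(x)
  ci <- which.max(nchar(x))  # ties: which.max takes the first
  center <- x[[ci]]
  others <- setdiff(seq_along(x), ci)
  if (length(unique(unname(x))) == 1) {
    return(locus_alignment(setNames(x, ids), locus_name))
  }
  pws <- lapply(others, function(i) .pairwise_affine(center, x[[i]], params))
  Lc <- nchar(center)
  # ins[[k]][j+1] = columns inserted after center position j (j = 0..Lc)
  ins_counts <- vapply(pws, function(pa) {
    cc <- strsplit(pa$center, "")[[1]]
    runs <- integer(Lc + 1)
    pos <- 0L
    run <- 0L
    for (ch in cc) {
      if (ch == "-") run <- run + 1L
      else {
        runs[pos + 1L] <- run
        run <- 0L
        pos <- pos + 1L
      }
    }
    runs[Lc + 1L] <- run
    runs
  }, integer(Lc + 1))
  ins_counts <- matrix(ins_counts, nrow = Lc + 1)
  g <- apply(ins_counts, 1, max)  # global insertion profile
  total_len <- Lc + sum(g)

  expand_center <- function() {
    cch <- strsplit(center, "")[[1]]
    out <- character(0)
    for (j in 0:Lc) {
      if (g[j + 1] > 0) out <- c(out, rep("-", g[j + 1]))
      if (j < Lc) out <- c(out, cch[j + 1])
    }
    paste(out, collapse = "")
  }
  expand_other <- function(k) {
    oc <- strsplit(pws[[k]]$other, "")[[1]]
    cc <- strsplit(pws[[k]]$center, "")[[1]]
    out <- character(0)
    pos <- 0L            # center positions consumed
    buf <- character(0)  # other chars pending in current insertion slot
    flush <- function(buf, slot) c(buf, rep("-", g[slot + 1] - length(buf)))
    for (i in seq_along(cc)) {
      if (cc[i] == "-") {
        buf <- c(buf, oc[i])
      } else {
        out <- c(out, flush(buf, pos), oc[i])
        buf <- character(0)
        pos <- pos + 1L
      }
    }
    out <- c(out, flush(buf, pos))
    paste(out, collapse = "")
  }
  rows <- character(length(x))
  rows[ci] <- expand_center()
  for (k in seq_along(others)) rows[others[k]] <- expand_other(k)
  stopifnot(all(nchar(rows) == total_len))
  locus_alignment(setNames(rows, ids), locus_name)
}

#' Screen a region catalogue across genomes
#'
#' For every catalogued region: extract from each genome where possible,
#' align the homologous copies, and score the alignment. Regions missing
#' from one or more genomes are still scored on the remaining records and
#' flagged `partial`; per-region failures are collected, not fatal. The
#' output is sorted by the [rank_loci()] score.
#'
#' @param genomes list of [genome_record] objects (>= 2).
#' @param catalogue a [region_catalogue].
#' @param params alignment parameters.
#' @param ssr_thresholds see [ssr_thresholds()].
#' @param weights ranking weights passed to [rank_loci()].
#' @return list with `report` (data.frame, one row per scored region, with
#'   `partial` flag), `alignments` (named list of `locus_alignment`) and
#'   `log` (character vector of per-region failures).
#' @export
screen_regions <- function(genomes, catalogue, params = align_params(),
                           ssr_thresholds = spacerscreen::ssr_thresholds(),
                           weights = c(subs = 1, ssr = 1)) {
  if (length(genomes) < 2) stop("need >= 2 genomes to screen", call. = FALSE)
  reports <- list()
  alignments <- list()
  log <- character(0)
  for (spec in catalogue) {
    seqs <- list()
    for (gn in genomes) {
      s <- tryCatch(extract_region(gn, spec), error = function(e) e)
      if (inherits(s, "error")) {
        log <- c(log, sprintf("%s / %s: %s", spec$name, gn$id,
                              conditionMessage(s)))
      } else if (!attr(s, "empty")) {
        seqs[[gn$id]] <- unclass(s)[[1]]
      } else {
        log <- c(log, sprintf("%s / %s: empty region", spec$name, gn$id))
      }
    }
    if (length(seqs) < 2) {
      log <- c(log, sprintf("%s: fewer than 2 extractable copies, skipped",
                            spec$name))
      next
    }
    aln <- align_homologs(dna_seqs(unlist(seqs)), params,
                          locus_name = spec$name)
    rep_row <- informativeness_report(aln, ssr_thresholds = ssr_thresholds)
    rep_row$partial <- length(seqs) < length(genomes)
    reports[[spec$name]] <- rep_row
    alignments[[spec$name]] <- aln
  }
  if (length(reports) == 0) {
    return(list(report = NULL, alignments = alignments, log = log))
  }
  report <- do.call(rbind, reports)
  ranking <- rank_loci(report, weights = weights)
  report <- report[match(ranking$locus_name, report$locus_name), ,
                   drop = FALSE]
  rownames(report) <- NULL
  list(report = report, alignments = alignments, log = log)
}
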