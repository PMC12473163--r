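# Locus ranking, supermatrix concatenation and export for external
# inference tools. Padding for taxa absent from a locus uses '?' (absent
# data), distinct from '-' (inferred gap); both are missing in statistics.

#' Rank loci by informativeness
#'
#' Score = `weights["subs"]` * substitutions per kb +
#' `weights["ssr"]` * SSR locus count, descending; ties broken
#' alphabetically by locus name.
#'
#' @param reports data.frame of [informativeness_report()] rows.
#' @param weights named numeric vector with elements `subs` and `ssr`.
#' @return `reports` augmented with `score` and `rank`, in rank order.
#' @export
rank_loci <- function(reports, weights = c(subs = 1, ssr = 1)) {
  if (nrow(reports) < 1) stop("no reports to rank", call. = FALSE)
  score <- weights[["subs"]] * reports$subs_per_kb +
    weights[["ssr"]] * reports$n_ssr
  ord <- order(-score, reports$locus_name)
  out <- reports[ord, , drop = FALSE]
  out$score <- score[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Concatenate locus alignments into a supermatrix
#'
#' Taxon sets may differ across loci: the supermatrix spans the union (in
#' first-seen order) and fills absent taxon-by-locus blocks with '?'.
#' Per-locus column spans are recorded as 0-based half-open offsets.
#'
#' @param alignments non-empty list of `locus_alignment` objects with unique
#'   locus names.
#' @return object of class `supermatrix`: list with `taxa`, `matrix`
#'   (character, taxa x total columns), `offsets` (data.frame `locus`,
#'   `start`, `end`), `total_length`.
#' @export
concatenate_loci <- function(alignments) {
  if (length(alignments) == 0) stop("no alignments to concatenate",
                                    call. = FALSE)
  nm <- vapply(alignments, function(a) a$locus_name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate locus names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  taxa <- character(0)
  for (a in alignments) taxa <- union(taxa, aln_taxa(a))
  lens <- vapply(alignments, function(a) a$length, integer(1))
  total <- sum(lens)
  m <- matrix("?", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens  # 0-based
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    m[aln_taxa(a), (starts[k] + 1):ends[k]] <- a$matrix
  }
  structure(list(taxa = taxa, matrix = m,
                 offsets = data.frame(locus = nm, start = starts, end = ends,
                                      stringsAsFactors = FALSE),
                 total_length = total),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d loci\n",
              length(x$taxa), x$total_length, nrow(x$offsets)))
  invisible(x)
}

#' Render a supermatrix (or one of its blocks) as a locus alignment
#'
#' @param sm a `supermatrix`.
#' @param locus optional locus name; default is the whole matrix.
#' @return a `locus_alignment`.
#' @export
sm_alignment <- function(sm, locus = NULL) {
  if (is.null(locus)) {
    return(locus_alignment(sm$matrix, locus_name = "supermatrix"))
  }
  o <- sm$offsets[sm$offsets$locus == locus, , drop = FALSE]
  if (nrow(o) != 1) stop("no such locus in supermatrix: ", locus,
                         call. = FALSE)
  locus_alignment(sm$matrix[, (o$start + 1):o$end, drop = FALSE],
                  locus_name = locus)
}

#' Export a supermatrix for external inference tools
#'
#' Writes a relaxed-PHYLIP alignment, a RAxML-style partition file and a
#' NEXUS matrix with charsets, all describing identical column spans in each
#' dialect's convention. Taxa consisting entirely of '?' are retained with a
#' warning.
#'
#' @param sm a `supermatrix`.
#' @param outdir output directory (created if needed).
#' @param basename file stem.
#' @return named character vector of the written paths, invisibly.
#' @export
export_for_inference <- function(sm, outdir, basename = "supermatrix") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_q <- rowSums(sm$matrix != "?") == 0
  if (any(all_q)) {
    warning("taxa with no data retained in export: ",
            paste(sm$taxa[all_q], collapse = ", "))
  }
  aln <- sm_alignment(sm)
  blocks <- lapply(sm$offsets$locus, function(l) sm_alignment(sm, l))
  paths <- c(
    phylip = file.path(outdir, paste0(basename, ".phy")),
    partitions = file.path(outdir, paste0(basename, ".partitions")),
    nexus = file.path(outdir, paste0(basename, ".nex")))
  write_phylip(aln, paths["phylip"])
  write_raxml_partitions(sm$offsets, paths["partitions"])
  write_nexus_matrix(blocks, paths["nexus"])
  invisible(paths)
}
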