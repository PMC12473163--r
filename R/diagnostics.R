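# Clade-diagnostic sites: parsimony-informative columns at which a named
# clade is fixed for a state absent from all other taxa. Two criteria are
# offered because "sites separating clade A from the rest" admits both:
#   fixed_difference - ingroup monomorphic for x, x absent outside;
#   strict           - additionally the complement is monomorphic (y != x).

#' Count clade-diagnostic parsimony-informative sites
#'
#' A column counts in `fixed_difference` mode when it is parsimony
#' informative, all non-missing ingroup rows share one state, and that state
#' is absent from every non-missing complement row; `strict` mode requires
#' the complement to be monomorphic as well. Rows missing at a column are
#' ignored; columns where either side has fewer than two non-missing rows
#' are skipped.
#'
#' @param aln a `locus_alignment`.
#' @param partition a [clade_partition]; the ingroup must be a strict,
#'   non-empty subset of the alignment's taxa.
#' @param mode "fixed_difference" (default) or "strict".
#' @return list with `count` and `sites`: data.frame with `column` (0-based),
#'   `clade_state`, `other_states`, `strict` flag.
#' @export
clade_pis <- function(aln, partition, mode = c("fixed_difference", "strict")) {
  mode <- match.arg(mode)
  taxa <- aln_taxa(aln)
  unknown <- setdiff(partition$ingroup, taxa)
  if (length(unknown) > 0) {
    stop("partition references unknown taxa: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ing <- intersect(taxa, partition$ingroup)
  out <- setdiff(taxa, ing)
  if (length(ing) < 2 || length(out) < 2) {
    warning(sprintf("partition '%s' leaves fewer than 2 taxa on one side; no diagnostic sites reported",
                    partition$name))
    return(list(count = 0L, sites = .empty_diag_sites()))
  }
  pis_sites <- count_pis(aln)$sites
  m <- aln$matrix
  rows <- list()
  for (col0 in pis_sites) {
    j <- col0 + 1L
    ci <- m[ing, j]; ci <- ci[ci %in% DNA_STATES]
    co <- m[out, j]; co <- co[co %in% DNA_STATES]
    if (length(ci) < 2 || length(co) < 2) next
    if (length(unique(ci)) != 1) next
    x <- ci[1]
    if (x %in% co) next
    is_strict <- length(unique(co)) == 1
    if (mode == "strict" && !is_strict) next
    rows[[length(rows) + 1]] <- data.frame(
      column = col0, clade_state = x,
      other_states = paste(sort(unique(co)), collapse = ","),
      strict = is_strict, stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else .empty_diag_sites()
  list(count = nrow(sites), sites = sites)
}

.empty_diag_sites <- function() {
  data.frame(column = integer(), clade_state = character(),
             other_states = character(), strict = logical(),
             stringsAsFactors = FALSE)
}

#' Per-locus table of clade-diagnostic site counts
#'
#' One row per locus with the diagnostic-site count in both modes and a
#' `none_detected` marker for loci where the ingroup shares no fixed
#' difference with the rest of the matrix.
#'
#' @param alignments named list of `locus_alignment` objects.
#' @param partition a [clade_partition].
#' @return data.frame with `locus_name`, `n_fixed_difference`, `n_strict`,
#'   `none_detected`, and a `sites` list-column of the fixed-difference
#'   site tables.
#' @export
clade_pis_table <- function(alignments, partition) {
  per_locus <- lapply(alignments, function(aln) {
    fd <- clade_pis(aln, partition, mode = "fixed_difference")
    list(row = data.frame(locus_name = aln$locus_name,
                          n_fixed_difference = fd$count,
                          n_strict = sum(fd$sites$strict),
                          none_detected = fd$count == 0L,
                          stringsAsFactors = FALSE),
         sites = fd$sites)
  })
  out <- do.call(rbind, lapply(per_locus, `[[`, "row"))
  rownames(out) <- NULL
  out$sites <- lapply(per_locus, `[[`, "sites")
  out
}
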