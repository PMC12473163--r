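# Per-locus informativeness statistics: indel events, transition/transversion
# substitutions, microsatellite (SSR) loci, and parsimony-informative sites.
# Conventions (documented in the methods vignette):
#   * gaps ('-'), '?' and IUPAC ambiguity codes are missing data everywhere;
#   * an indel event is a maximal gap run; runs with identical coordinates in
#     several rows are one event (simple indel coding);
#   * substitutions are counted per column against the column consensus, one
#     count per distinct non-consensus state;
#   * terminal gap runs are excluded by default (ragged Sanger read ends).

TRANSITION_PAIRS <- list(c("A", "G"), c("C", "T"))

.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Find indel events in an alignment
#'
#' Per row, maximal runs of '-' are candidate events; runs with identical
#' (start, end) across rows are collapsed into one event carrying the pooled
#' set of taxa. Leading and trailing runs are treated as missing sequence
#' ends and excluded unless `include_terminal = TRUE`.
#'
#' @param aln a `locus_alignment`.
#' @param include_terminal count terminal gap runs as events.
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   alignment columns), `length`, `carriers` (comma-separated taxon ids)
#'   and `n_carriers`; zero rows when the alignment is gap-free.
#' @export
find_indels <- function(aln, include_terminal = FALSE) {
  m <- aln$matrix
  events <- list()
  for (tx in rownames(m)) {
    r <- rle(m[tx, ] == "-")
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    gap <- which(r$values)
    if (!include_terminal) {
      gap <- gap[gap != 1 & gap != length(r$values)]
    }
    for (g in gap) {
      key <- sprintf("%d:%d", starts[g], ends[g])
      events[[key]] <- c(events[[key]], tx)
    }
  }
  if (length(events) == 0) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      carriers = character(), n_carriers = integer(),
                      stringsAsFactors = FALSE))
  }
  se <- do.call(rbind, strsplit(names(events), ":"))
  out <- data.frame(start = as.integer(se[, 1]), end = as.integer(se[, 2]),
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out$carriers <- vapply(events, function(x) paste(sort(x), collapse = ","),
                         character(1))
  out$n_carriers <- lengths(events)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count transition and transversion substitutions
#'
#' Per column, the consensus is the most frequent unambiguous state (ties
#' broken alphabetically); each distinct non-consensus state contributes one
#' substitution, classified as a transition (A<->G, C<->T) or transversion.
#'
#' @param aln a `locus_alignment`.
#' @return named integer vector `c(transitions = , transversions = )`.
#' @export
count_substitutions <- function(aln) {
  cnt <- .state_counts(aln$matrix)           # 4 x L counts of A,C,G,T
  cons <- max.col(t(cnt), ties.method = "first")  # alphabetical tie-break
  present <- cnt > 0
  purine <- c(TRUE, FALSE, TRUE, FALSE)      # A,C,G,T
  ti <- 0L; tv <- 0L
  for (k in 1:4) {
    other <- present[k, ] & cons != k
    is_ti <- purine[k] == purine[cons]
    ti <- ti + sum(other & is_ti)
    tv <- tv + sum(other & !is_ti)
  }
  c(transitions = ti, transversions = tv)
}

# per-column counts of the four unambiguous states, as a 4 x ncol matrix
.state_counts <- function(m) {
  rbind(A = colSums(m == "A"), C = colSums(m == "C"),
        G = colSums(m == "G"), T = colSums(m == "T"))
}

#' Default SSR detection thresholds
#'
#' Minimum repeat counts per motif length (1-6 bp). These are configuration
#' defaults of this package, not a claim about any external tool's settings.
#'
#' @return named integer vector, names "1".."6".
#' @export
ssr_thresholds <- function() {
  c("1" = 10L, "2" = 6L, "3" = 4L, "4" = 3L, "5" = 3L, "6" = 3L)
}

.canonical_rotation <- function(motif) {
  n <- nchar(motif)
  if (n == 1) return(motif)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(motif, i, n), substr(motif, 1, i - 1)), character(1))
  min(rots)
}

.is_primitive <- function(motif) {
  n <- nchar(motif)
  if (n == 1) return(TRUE)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0 &&
        identical(strrep(substr(motif, 1, p), n / p), motif)) return(FALSE)
  }
  TRUE
}

#' Find microsatellite arrays in one sequence
#'
#' Detects all maximal perfect tandem arrays of 1-6 bp motifs meeting the
#' repeat-count thresholds. Motifs are reported in canonical (lexicographically
#' smallest) rotation; arrays whose motif is a power of a shorter motif are
#' reported once under the shortest motif; overlapping reports are suppressed
#' in favour of the longer array. Gaps, 'N' and ambiguity codes break arrays.
#'
#' @param seq a residue string (degap aligned rows first) or a single-element
#'   [dna_seqs].
#' @param thresholds named vector of minimum repeat counts per motif length.
#' @return data.frame with `motif` (canonical), `repeats`, `start`, `end`
#'   (0-based half-open in `seq`), `length` (= repeats * motif length).
#' @export
find_ssr <- function(seq, thresholds = ssr_thresholds()) {
  s <- if (inherits(seq, "dna_seqs")) unclass(seq)[[1]] else seq
  s <- toupper(s)
  chars <- strsplit(s, "")[[1]]
  ok <- chars %in% DNA_STATES
  L <- length(chars)
  c_motif <- character(0); c_reps <- integer(0); c_start <- integer(0)
  for (m in 1:6) {
    if (L < 2 * m) next
    min_rep <- thresholds[[as.character(m)]]
    eq <- chars[seq_len(L - m)] == chars[(m + 1):L] &
      ok[seq_len(L - m)] & ok[(m + 1):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      arr_len <- r$lengths[k] + m        # full self-matching stretch
      reps <- (arr_len %/% m)
      if (reps < min_rep) next
      i0 <- starts[k]                     # 1-based array start
      motif <- paste(chars[i0:(i0 + m - 1)], collapse = "")
      if (!.is_primitive(motif)) next
      c_motif <- c(c_motif, .canonical_rotation(motif))
      c_reps <- c(c_reps, reps)
      c_start <- c(c_start, i0 - 1L)
    }
  }
  if (length(c_motif) == 0) {
    return(data.frame(motif = character(), repeats = integer(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  cand <- data.frame(motif = c_motif, repeats = c_reps, start = c_start,
                     end = c_start + c_reps * nchar(c_motif),
                     length = c_reps * nchar(c_motif),
                     stringsAsFactors = FALSE)
  # longest-array-wins overlap suppression; deterministic tie-break
  cand <- cand[order(-cand$length, cand$start, nchar(cand$motif)), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cand)) > i)
    if (length(later) == 0) next
    ov <- cand$start[later] < cand$end[i] & cand$end[later] > cand$start[i]
    keep[later[ov]] <- FALSE
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count merged SSR loci in an alignment
#'
#' Runs [find_ssr()] on every degapped row, maps the arrays back to alignment
#' columns, and merges loci from different rows that share a canonical motif
#' and overlap in alignment coordinates into one counted locus.
#'
#' @param aln a `locus_alignment`.
#' @param thresholds see [ssr_thresholds()].
#' @return list with `count` and `loci` (data.frame with `carrier`, `motif`,
#'   `repeats`, `aln_start`, `aln_end`, `locus_id`).
#' @export
count_ssr_loci <- function(aln, thresholds = ssr_thresholds()) {
  m <- aln$matrix
  rows <- list()
  for (tx in rownames(m)) {
    r <- m[tx, ]
    keep <- !(r %in% c("-", "?"))
    if (!any(keep)) next
    degapped <- paste(r[keep], collapse = "")
    pos <- which(keep)  # degapped index -> 1-based alignment column
    hits <- find_ssr(degapped, thresholds)
    if (nrow(hits) == 0) next
    hits$carrier <- tx
    hits$aln_start <- pos[hits$start + 1L] - 1L
    hits$aln_end <- pos[hits$end]          # half-open
    rows[[tx]] <- hits
  }
  if (length(rows) == 0) {
    return(list(count = 0L, loci = data.frame(
      carrier = character(), motif = character(), repeats = integer(),
      aln_start = integer(), aln_end = integer(), locus_id = integer(),
      stringsAsFactors = FALSE)))
  }
  loci <- do.call(rbind, rows)
  loci <- loci[order(loci$motif, loci$aln_start, loci$carrier), , drop = FALSE]
  # merge same-motif overlapping intervals (transitive)
  loci$locus_id <- NA_integer_
  next_id <- 0L
  for (mt in unique(loci$motif)) {
    idx <- which(loci$motif == mt)
    cur_end <- -1L
    for (i in idx) {
      if (loci$aln_start[i] < cur_end) {
        loci$locus_id[i] <- next_id
        cur_end <- max(cur_end, loci$aln_end[i])
      } else {
        next_id <- next_id + 1L
        loci$locus_id[i] <- next_id
        cur_end <- loci$aln_end[i]
      }
    }
  }
  rownames(loci) <- NULL
  list(count = length(unique(loci$locus_id)),
       loci = loci[, c("carrier", "motif", "repeats", "aln_start", "aln_end",
                       "locus_id")])
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' states each occur in at least two rows; gaps, '?' and ambiguity codes are
#' missing data.
#'
#' @param aln a `locus_alignment`.
#' @return list with `count` and `sites` (0-based column indices).
#' @export
count_pis <- function(aln) {
  cnt <- .state_counts(aln$matrix)
  sites <- which(colSums(cnt >= 2) >= 2) - 1L
  list(count = length(sites), sites = sites)
}

#' Per-locus informativeness report
#'
#' Assembles aligned length, indel events and total indel bp, transitions,
#' transversions, merged SSR loci and parsimony-informative sites, plus
#' per-kb rates, into a one-row data.frame.
#'
#' @param aln a `locus_alignment`.
#' @param ssr_thresholds see [ssr_thresholds()].
#' @param include_terminal count terminal gap runs as indel events.
#' @return one-row data.frame.
#' @export
informativeness_report <- function(aln, ssr_thresholds = spacerscreen::ssr_thresholds(),
                                   include_terminal = FALSE) {
  ind <- find_indels(aln, include_terminal = include_terminal)
  subs <- count_substitutions(aln)
  ssr <- count_ssr_loci(aln, ssr_thresholds)
  pis <- count_pis(aln)
  kb <- aln$length / 1000
  data.frame(
    locus_name = aln$locus_name,
    length = aln$length,
    n_indels = nrow(ind),
    indel_bp = sum(ind$length),
    transitions = unname(subs["transitions"]),
    transversions = unname(subs["transversions"]),
    n_ssr = ssr$count,
    n_pis = pis$count,
    indels_per_kb = nrow(ind) / kb,
    subs_per_kb = sum(subs) / kb,
    ssr_per_kb = ssr$count / kb,
    pis_per_kb = pis$count / kb,
    stringsAsFactors = FALSE)
}
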