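#' @importFrom stats setNames
NULL

# Character conventions used throughout:
#   '-'  alignment gap (treated as missing in all statistics)
#   '?'  absent data introduced by supermatrix padding (also missing)
#   'N' and IUPAC ambiguity codes: missing in all statistics
# All intervals are 0-based half-open internally; conversion to the 1-based
# inclusive convention happens only at format boundaries (GenBank, NEXUS,
# RAxML partition files).

IUPAC_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
DNA_STATES <- c("A", "C", "G", "T")
MISSING_CHARS <- c("-", "?", IUPAC_AMBIG)

.norm_residues <- function(x, what = "sequence") {
  x <- toupper(gsub("[[:space:]]", "", x))
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(DNA_STATES, MISSING_CHARS))
  if (length(bad) > 0) {
    stop(sprintf("invalid %s characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Create a set of named DNA sequences
#'
#' The basic unaligned sequence container: a named character vector of residue
#' strings over the DNA alphabet (plus gap, '?', N and IUPAC ambiguity codes),
#' normalised to upper case. Names are taxon or accession labels and must be
#' unique and non-empty.
#'
#' @param residues character vector of residue strings.
#' @param ids character vector of unique labels (defaults to `names(residues)`).
#' @param descriptions optional free-text descriptions, recycled to length.
#' @return a named character vector of class `dna_seqs` with a `descriptions`
#'   attribute.
#' @export
dna_seqs <- function(residues, ids = names(residues), descriptions = NULL) {
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence needs a non-empty id", call. = FALSE)
  }
  ids <- trimws(gsub("[[:space:]]+", " ", ids))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  residues <- vapply(residues, .norm_residues, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(residues))) stop("empty sequence residues", call. = FALSE)
  out <- setNames(residues, ids)
  attr(out, "descriptions") <-
    if (is.null(descriptions)) rep("", length(out)) else
      rep_len(as.character(descriptions), length(out))
  class(out) <- "dna_seqs"
  out
}

#' @export
print.dna_seqs <- function(x, ...) {
  cat(sprintf("%d DNA sequence(s), lengths %s\n", length(x),
              paste(range(nchar(unclass(x))), collapse = "-")))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Residues are upper-cased; gap characters are preserved, so pre-aligned
#' FASTA is accepted. Duplicate ids and malformed records are errors.
#'
#' @param path path to a FASTA file.
#' @return a [dna_seqs] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    stop(sprintf("malformed FASTA (%s line 1): expected '>' header", path),
         call. = FALSE)
  }
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S*\\s*", "", headers))
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1),
                 collapse = "")
  if (length(seqs) != length(ids)) {
    empty <- which(!(seq_along(ids) %in% as.integer(names(seqs))))[1]
    stop(sprintf("malformed FASTA (%s line %d): record '%s' has no residues",
                 path, which(hdr)[empty], ids[empty]), call. = FALSE)
  }
  dna_seqs(unname(seqs), ids = ids, descriptions = desc)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [dna_seqs] object or named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  ids <- names(seqs)
  desc <- attr(seqs, "descriptions")
  if (is.null(desc)) desc <- rep("", length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- if (nzchar(desc[i])) paste(ids[i], desc[i]) else ids[i]
    writeLines(paste0(">", hdr), con)
    s <- unclass(seqs)[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a locus alignment
#'
#' An aligned set of sequences for one locus, stored as a taxon-by-column
#' character matrix. All rows must have equal length; the only gap character
#' is '-' ('?' is additionally allowed for supermatrix padding).
#'
#' @param seqs a [dna_seqs] object, named character vector of equal-length
#'   strings, or a character matrix with taxon rownames.
#' @param locus_name name of the locus (e.g. "rps16-trnK").
#' @return an object of class `locus_alignment`: list with `locus_name`,
#'   `matrix` (character, rownames = taxon ids) and `length` (columns).
#' @export
locus_alignment <- function(seqs, locus_name = "locus") {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
    if (is.null(rownames(m))) stop("alignment matrix needs taxon rownames",
                                   call. = FALSE)
  } else {
    if (is.null(names(seqs))) stop("aligned sequences need taxon ids",
                                   call. = FALSE)
    lens <- nchar(unclass(seqs))
    if (length(unique(lens)) != 1) {
      stop(sprintf("rows of '%s' differ in length (%s)", locus_name,
                   paste(unique(lens), collapse = ", ")), call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(unclass(seqs)), ""))
    rownames(m) <- names(seqs)
  }
  if (ncol(m) < 1) stop("alignment must have at least one column",
                        call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate taxon ids in alignment",
                                       call. = FALSE)
  bad <- setdiff(unique(as.vector(m)), c(DNA_STATES, MISSING_CHARS))
  if (length(bad) > 0) {
    stop("invalid alignment characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(locus_name = locus_name, matrix = m, length = ncol(m)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d taxa x %d columns\n",
              x$locus_name, nrow(x$matrix), x$length))
  invisible(x)
}

#' Taxon labels of an alignment
#' @param aln a `locus_alignment`.
#' @return character vector of taxon ids.
#' @export
aln_taxa <- function(aln) rownames(aln$matrix)

#' Collapse an alignment back to (gapped) sequence strings
#' @param aln a `locus_alignment`.
#' @param degap drop '-'/'?' characters per row first.
#' @return a named character vector.
#' @export
aln_strings <- function(aln, degap = FALSE) {
  out <- apply(aln$matrix, 1, function(r) {
    if (degap) r <- r[!r %in% c("-", "?")]
    paste(r, collapse = "")
  })
  setNames(out, rownames(aln$matrix))
}

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet plus '-' and '?'.
#'
#' @param x a single residue string.
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B", D = "H",
            H = "D", "-" = "-", "?" = "?")
  chars <- rev(strsplit(toupper(x), "")[[1]])
  paste(unname(comp[chars]), collapse = "")
}

#' Define a named clade bipartition
#'
#' A named split of the taxon set into an ingroup and (implicitly) everything
#' else, used for diagnostic-site counting.
#'
#' @param name label for the split (e.g. "acinos_ziziphora").
#' @param ingroup character vector of taxon ids, non-empty.
#' @return an object of class `clade_partition`.
#' @export
clade_partition <- function(name, ingroup) {
  ingroup <- unique(trimws(ingroup))
  if (length(ingroup) == 0) stop("ingroup must be non-empty", call. = FALSE)
  structure(list(name = name, ingroup = ingroup), class = "clade_partition")
}

# TRUE where the alignment matrix holds a real (A/C/G/T) state.
.state_ok <- function(m) {
  matrix(m %in% DNA_STATES, nrow = nrow(m), dimnames = dimnames(m))
}
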