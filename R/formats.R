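# Hand-off formats for external inference tools. Column bookkeeping follows
# each dialect's convention: NEXUS charsets and RAxML partition lines are
# 1-based inclusive; everything internal stays 0-based half-open.

.nexus_label <- function(x) {
  ifelse(grepl("[[:space:]()\\[\\];,=]", x), paste0("'", x, "'"), x)
}

#' Write a partitioned NEXUS matrix
#'
#' Concatenates the given locus alignments (which must share an identical
#' taxon set) into one DATA block and writes a SETS block with one charset
#' per locus in NEXUS's 1-based inclusive coordinates.
#'
#' @param alignments non-empty list of `locus_alignment` objects sharing a
#'   taxon set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(alignments, path) {
  if (length(alignments) == 0) stop("no alignments to write", call. = FALSE)
  taxa <- aln_taxa(alignments[[1]])
  for (a in alignments) {
    miss <- c(setdiff(taxa, aln_taxa(a)), setdiff(aln_taxa(a), taxa))
    if (length(miss) > 0) {
      stop("taxon sets differ across loci; missing/extra: ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
    }
  }
  lens <- vapply(alignments, function(a) a$length, integer(1))
  total <- sum(lens)
  rows <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(a)
      paste(a$matrix[tx, ], collapse = ""), character(1)), collapse = "")
  }, character(1))
  labs <- .nexus_label(taxa)
  pad <- max(nchar(labs)) + 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa), total),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
               "  MATRIX"), con)
  writeLines(sprintf("    %-*s%s", pad, labs, rows), con)
  writeLines(c("  ;", "END;", "BEGIN SETS;"), con)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  nm <- vapply(alignments, function(a) a$locus_name, character(1))
  writeLines(sprintf("  CHARSET %s = %d-%d;", gsub("[[:space:]]", "_", nm),
                     starts, ends), con)
  writeLines(c("END;"), con)
  invisible(path)
}

#' Read a partitioned NEXUS matrix
#'
#' Counterpart of [write_nexus_matrix()]: parses the DATA block and the
#' charsets and returns one `locus_alignment` per charset (or a single
#' alignment spanning everything when no SETS block is present).
#'
#' @param path path to a NEXUS file.
#' @return named list of `locus_alignment` objects.
#' @export
read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^#NEXUS", lines[1], ignore.case = TRUE)) {
    stop("not a NEXUS file: ", path, call. = FALSE)
  }
  mstart <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1]
  if (is.na(mstart)) stop("NEXUS file has no MATRIX block", call. = FALSE)
  mend <- grep("^\\s*;", lines)
  mend <- mend[mend > mstart][1]
  body <- trimws(lines[(mstart + 1):(mend - 1)])
  body <- body[nzchar(body)]
  parse_row <- function(ln) {
    if (startsWith(ln, "'")) {
      m <- regexec("^'([^']*)'\\s+(\\S+)$", ln)[[1]]
      id <- regmatches(ln, regexec("^'([^']*)'\\s+(\\S+)$", ln))[[1]]
      c(id[2], id[3])
    } else {
      m <- strsplit(ln, "\\s+")[[1]]
      c(m[1], paste(m[-1], collapse = ""))
    }
  }
  parsed <- vapply(body, parse_row, character(2))
  seqs <- setNames(parsed[2, ], parsed[1, ])
  cs_lines <- grep("^\\s*CHARSET", lines, ignore.case = TRUE, value = TRUE)
  full <- locus_alignment(seqs, locus_name = "matrix")
  if (length(cs_lines) == 0) return(list(matrix = full))
  out <- list()
  for (cl in cs_lines) {
    m <- regmatches(cl, regexec(
      "CHARSET\\s+(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)", cl,
      ignore.case = TRUE))[[1]]
    nm <- m[2]
    s <- as.integer(m[3]); e <- as.integer(m[4])
    out[[nm]] <- locus_alignment(full$matrix[, s:e, drop = FALSE],
                                 locus_name = nm)
  }
  out
}

#' Write a relaxed PHYLIP alignment
#'
#' @param aln a `locus_alignment` (or supermatrix rendered as one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  taxa <- gsub("[[:space:]]+", "_", aln_taxa(aln))
  rows <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(aln$matrix), aln$length), con)
  writeLines(sprintf("%-*s  %s", max(nchar(taxa)), taxa, rows), con)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One "DNA, name = start-end" line per locus, 1-based inclusive.
#'
#' @param offsets data.frame with columns `locus`, `start`, `end` (0-based
#'   half-open, as stored on a supermatrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raxml_partitions <- function(offsets, path) {
  writeLines(sprintf("DNA, %s = %d-%d",
                     gsub("[[:space:]]", "_", offsets$locus),
                     offsets$start + 1L, offsets$end), path)
  invisible(path)
}

# Newick leaf labels containing spaces are quoted on write and unquoted on
# read (ape itself does not handle quoted labels); support values live as
# internal-node labels, the usual RAxML/BEAST convention.

.SPACE_TOKEN <- "@SP@"

#' Read a Newick tree
#'
#' @param path path to a Newick file, or a Newick string.
#' @return an [ape::read.tree] "phylo" object; quoted labels are unescaped.
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "") else path
  if (!grepl(";\\s*$", txt)) stop("Newick parse error: missing ';'",
                                  call. = FALSE)
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) {
    stop(sprintf("Newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
                 n_open, n_close), call. = FALSE)
  }
  # protect quoted labels: 'a b' -> a@SP@b, then strip the quotes
  m <- gregexpr("'[^']*'", txt)[[1]]
  if (m[1] != -1) {
    pieces <- regmatches(txt, gregexpr("'[^']*'", txt))[[1]]
    fixed <- gsub(" ", .SPACE_TOKEN, gsub("'", "", pieces), fixed = TRUE)
    for (i in seq_along(pieces)) txt <- sub(pieces[i], fixed[i], txt,
                                            fixed = TRUE)
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("Newick parse error in: ", substr(txt, 1, 60),
                        call. = FALSE)
  tr$tip.label <- gsub(.SPACE_TOKEN, " ", tr$tip.label, fixed = TRUE)
  tr
}

#' Write a Newick tree
#'
#' @param tree a "phylo" object.
#' @param path output path; if `NULL` the Newick string is returned.
#' @return the path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  tr <- tree
  needs_quote <- grepl(" ", tr$tip.label)
  tr$tip.label[needs_quote] <- gsub(" ", .SPACE_TOKEN,
                                    tr$tip.label[needs_quote])
  txt <- ape::write.tree(tr)
  txt <- gsub(paste0("([(,])([^(),:]*", .SPACE_TOKEN, "[^(),:]*)"),
              "\\1'\\2'", txt)
  txt <- gsub(.SPACE_TOKEN, " ", txt, fixed = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
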