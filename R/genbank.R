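# GenBank flat-file parsing. Only the pieces needed for region harvesting are
# modelled: the accession, the ORIGIN sequence, and gene/tRNA/rRNA/CDS/intron/
# exon features with their locations. join() locations on a single strand are
# kept as ordered feature parts (needed for intron extraction); order() and
# mixed-strand joins (trans-splicing) are rejected.

#' Construct an annotated genome record
#'
#' @param id accession string.
#' @param residues DNA string.
#' @param features data.frame with columns `type`, `gene`, `start`, `end`
#'   (0-based half-open), `strand` ('+'/'-') and optionally `feature_id`,
#'   `part` for multi-exon features.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, residues, features) {
  residues <- .norm_residues(residues, "genome")
  stopifnot(is.data.frame(features))
  if (is.null(features$feature_id)) features$feature_id <- seq_len(nrow(features))
  if (is.null(features$part)) features$part <- 1L
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  n <- nchar(residues)
  with(features, {
    if (any(start < 0 | end > n | start >= end)) {
      stop("feature interval outside sequence bounds", call. = FALSE)
    }
  })
  need_name <- features$type %in% c("gene", "tRNA")
  if (any(need_name & !nzchar(features$gene))) {
    stop("gene/tRNA features must carry a gene name", call. = FALSE)
  }
  structure(list(id = id, residues = residues,
                 features = features[order(features$start), , drop = FALSE]),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d feature part(s)\n",
              x$id, nchar(x$residues), nrow(x$features)))
  invisible(x)
}

# "10..20" / "complement(10..20)" / "join(...)" -> list(strand, parts matrix)
.parse_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  if (grepl("order\\(", loc)) {
    stop("compound order() location not supported: ", loc, call. = FALSE)
  }
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  if (any(grepl("complement", parts))) {
    if (strand == "-") stop("nested complement in location", call. = FALSE)
    if (!all(grepl("^complement\\(", parts))) {
      stop("trans-spliced (mixed-strand) location not supported: ", loc,
           call. = FALSE)
    }
    strand <- "-"
    parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
  }
  iv <- t(vapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 0) {
      m <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
      if (length(m) == 0) stop("unparseable location part: ", p, call. = FALSE)
      m <- c(m, m[2])
    }
    as.integer(m[2:3])
  }, integer(2)))
  # 1-based inclusive -> 0-based half-open
  cbind(start = iv[, 1] - 1L, end = iv[, 2]) -> iv2
  list(strand = strand, parts = iv2)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Captures gene, tRNA, rRNA, CDS, exon and intron features. Coordinates are
#' converted from GenBank's 1-based inclusive convention to 0-based half-open
#' intervals. A missing ORIGIN sequence is an error.
#'
#' @param path path to a GenBank flat file (single record).
#' @return a [genome_record].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  acc <- grep("^(ACCESSION|LOCUS)", lines, value = TRUE)
  id <- if (length(acc)) strsplit(trimws(acc[1]), "\\s+")[[1]][2] else
    basename(path)

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0) stop("GenBank record has no ORIGIN sequence",
                                call. = FALSE)
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ostart[1] + 1):(oend - 1)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(residues)) stop("GenBank record has empty ORIGIN sequence",
                              call. = FALSE)

  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1):(ostart[1] - 1)]
    is_key <- grepl("^ {2,8}\\S", block) & !grepl("^ {10,}", block)
    key_idx <- which(is_key)
    keep <- c("gene", "tRNA", "rRNA", "CDS", "exon", "intron")
    fid <- 0L
    for (k in seq_along(key_idx)) {
      i <- key_idx[k]
      key <- sub("^\\s*(\\S+).*$", "\\1", block[i])
      stop_at <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(block)
      body <- block[i:stop_at]
      if (!key %in% keep) next
      # location = feature line remainder plus continuation lines w/o '/'
      loc <- sub("^\\s*\\S+\\s+", "", body[1])
      j <- 2
      while (j <= length(body) && !grepl("^\\s*/", body[j])) {
        loc <- paste0(loc, trimws(body[j]))
        j <- j + 1
      }
      quals <- body[grepl("^\\s*/", body)]
      gene <- ""
      g <- grep("^\\s*/gene=", quals, value = TRUE)
      if (length(g)) gene <- gsub("\"", "", sub("^\\s*/gene=", "", g[1]))
      parsed <- .parse_location(loc)
      fid <- fid + 1L
      feats[[fid]] <- data.frame(
        type = key, gene = gene,
        start = parsed$parts[, "start"], end = parsed$parts[, "end"],
        strand = parsed$strand, feature_id = fid,
        part = seq_len(nrow(parsed$parts)), stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(type = character(), gene = character(), start = integer(),
               end = integer(), strand = character(), feature_id = integer(),
               part = integer(), stringsAsFactors = FALSE)
  genome_record(id, residues, features)
}

#' Normalise an annotated gene name for matching
#'
#' tRNA anticodon suffixes in their common dialects ("trnK-UUU", "trnK(UUU)",
#' "trnK_UUU") are stripped so that annotation variants match the same
#' catalogue entry; other names pass through unchanged.
#'
#' @param x character vector of gene names.
#' @return normalised names.
#' @export
norm_gene_name <- function(x) {
  x <- trimws(x)
  trna <- grepl("^trn", x, ignore.case = TRUE)
  x[trna] <- sub("[-_ ]?\\(?[ACGUacgu]{3}\\)?$", "", x[trna])
  x
}
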