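# The candidate-region catalogue used for the in-silico screen of plastome
# records: 43 intergenic spacers and 6 introns that are routinely surveyed
# when choosing variable chloroplast markers in Lamiaceae and other
# angiosperms. Display names keep tRNA anticodons; matching uses normalised
# gene names (see norm_gene_name).

#' Define a candidate region
#'
#' @param name canonical region name: "geneA-geneB" for spacers,
#'   "geneX intron k" for introns.
#' @param kind "spacer" or "intron".
#' @param flank_genes for spacers: the two flanking gene names as annotated.
#'   They are normally distinct; the special region between the two exon
#'   copies of a single tRNA gene (e.g. "trnK-matK-trnK") uses the same gene
#'   twice, and extraction then takes the two nearest distinct copies.
#' @param host_gene for introns: the gene carrying the intron.
#' @param intron_ordinal for introns: which intron (1-based, >= 1).
#' @param display optional pretty name (anticodons etc.).
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(name, kind = c("spacer", "intron"),
                        flank_genes = NULL, host_gene = NULL,
                        intron_ordinal = 1L, display = name) {
  kind <- match.arg(kind)
  if (kind == "spacer") {
    if (length(flank_genes) != 2) {
      stop("spacer needs two flank genes", call. = FALSE)
    }
  } else {
    if (is.null(host_gene) || !nzchar(host_gene)) {
      stop("intron needs a host gene", call. = FALSE)
    }
    if (intron_ordinal < 1) stop("intron ordinal must be >= 1", call. = FALSE)
  }
  structure(list(name = name, kind = kind, flank_genes = flank_genes,
                 host_gene = host_gene,
                 intron_ordinal = as.integer(intron_ordinal),
                 display = display),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s (%s)\n", x$display, x$kind))
  invisible(x)
}

.spacer <- function(a, b, display = paste0(a, "-", b),
                    name = paste0(norm_gene_name(a), "-", norm_gene_name(b))) {
  region_spec(name, "spacer", flank_genes = c(a, b), display = display)
}

.intron <- function(host, k = 1L, name = if (k > 1 || host == "clpP")
  sprintf("%s intron %d", host, k) else paste(host, "intron")) {
  region_spec(name, "intron", host_gene = host, intron_ordinal = k)
}

#' The built-in candidate-region catalogue
#'
#' 49 plastome regions: 43 intergenic spacers and 6 introns, the standard
#' screen set for selecting variable chloroplast markers. Names are unique
#' after gene-name normalisation; directional duplicates (e.g. "rpl32-trnL"
#' and "trnL-rpl32") are distinct entries because they are annotated from
#' different reference orientations.
#'
#' @return an object of class `region_catalogue`: a named list of
#'   [region_spec] objects.
#' @export
builtin_catalogue <- function() {
  specs <- list(
    .spacer("accD", "psaI"),
    .spacer("atpB", "rbcL"),
    .spacer("rpl32", "trnL-UAG", display = "rpl32-trnL(UAG)"),
    .spacer("atpF", "atpH"),
    .spacer("atpI", "atpH"),
    .spacer("trnL-UAA", "trnF-GAA", display = "trnL(UAA)-trnF(GAA)"),
    .spacer("ccsA", "ndhD"),
    .spacer("clpP", "psbB"),
    .spacer("ndhC", "trnV-UAC", display = "ndhC-trnV(UAC)"),
    .spacer("ndhE", "ndhI"),
    .spacer("petA", "psbJ"),
    .spacer("petB", "petD"),
    .spacer("petL", "psaJ"),
    .spacer("petN", "psbM"),
    .spacer("psaA", "ycf3"),
    .spacer("psaC", "ndhE"),
    .spacer("psaI", "ycf4"),
    .spacer("psaJ", "rpl20"),
    .spacer("psbA", "trnH-GUG", display = "psbA-trnH(GUG)"),
    .spacer("psbK", "trnS-UGA", display = "psbK-trnS(UGA)"),
    .spacer("rbcL", "accD"),
    .spacer("rpl20", "rps12"),
    .spacer("rpl23", "psbA"),
    .spacer("rps3", "rps19"),
    .spacer("rps4", "trnT"),
    .spacer("rps16", "trnQ-UUG", display = "rps16-trnQ(UUG)"),
    .spacer("rps15", "ycf1"),
    .spacer("rps16", "trnK-UUU", display = "rps16-trnK(UUU)"),
    .spacer("rrn23", "trnA"),
    .spacer("trnC", "trnD"),
    .spacer("trnD", "trnT"),
    .spacer("trnF", "ndhJ"),
    .spacer("trnF", "psbA"),
    .spacer("trnG", "atpA"),
    .spacer("trnH-GUG", "trnK-UUU", display = "trnH(GUG)-trnK(UUU)"),
    region_spec("trnK-matK-trnK", "spacer",
                flank_genes = c("trnK-UUU", "trnK-UUU"),
                display = "trnK(UUU)-matK-trnK(UUU)"),
    .spacer("trnK-UUU", "trnQ-UUG", display = "trnK(UUU)-trnQ(UUG)"),
    .spacer("trnL-UAG", "rpl32", display = "trnL(UAG)-rpl32"),
    .spacer("trnQ-UUG", "psbK", display = "trnQ(UUG)-psbK"),
    .spacer("trnS-UGA", "psbZ", display = "trnS(UGA)-psbZ"),
    .spacer("trnT", "psbC"),
    .spacer("ycf3", "trnS-UGA", display = "ycf3-trnS(UGA)"),
    .spacer("ycf4", "ycf10"),
    .intron("atpF"),
    .intron("clpP", 1L),
    .intron("clpP", 2L),
    .intron("rpoC1"),
    .intron("trnV"),
    .intron("ycf3", 1L, name = "ycf3 intron 1")
  )
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("catalogue names not unique", call. = FALSE)
  structure(setNames(specs, nm), class = "region_catalogue")
}

#' @export
print.region_catalogue <- function(x, ...) {
  kinds <- vapply(x, function(s) s$kind, character(1))
  cat(sprintf("<region_catalogue> %d regions (%d spacers, %d introns)\n",
              length(x), sum(kinds == "spacer"), sum(kinds == "intron")))
  invisible(x)
}
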