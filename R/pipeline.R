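# One-call orchestration: loci (loaded or simulated) -> informativeness
# stats -> clade diagnostics -> ranking -> supermatrix -> NJ tree with
# bootstrap, with a machine-readable manifest of every artifact written.

.known_keys <- c("loci_dir", "simulate", "ssr_thresholds", "clades",
                 "weights", "top_k", "bootstrap", "outdir")

#' Validate a pipeline run configuration
#'
#' @param config named list (or path to a YAML file with the same keys):
#'   `outdir` (required), exactly one of `loci_dir` (directory of aligned
#'   per-locus FASTA files) or `simulate` (list with `seed`), and optionally
#'   `ssr_thresholds`, `clades` (named list: clade name -> taxon ids),
#'   `weights` (`subs`, `ssr`), `top_k`, `bootstrap` (`reps`, `seed`,
#'   `model`, `outgroup`). Unknown keys are rejected.
#' @return the normalised config list, invisibly on success.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), .known_keys)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$outdir)) stop("config needs 'outdir'", call. = FALSE)
  has_dir <- !is.null(config$loci_dir)
  has_sim <- !is.null(config$simulate)
  if (has_dir == has_sim) {
    stop("config needs exactly one of 'loci_dir' or 'simulate'",
         call. = FALSE)
  }
  if (has_dir && !dir.exists(config$loci_dir)) {
    stop("loci_dir does not exist: ", config$loci_dir, call. = FALSE)
  }
  if (has_sim && is.null(config$simulate$seed)) {
    stop("simulate config needs 'seed'", call. = FALSE)
  }
  if (!is.null(config$clades)) {
    if (is.null(names(config$clades)) || any(!nzchar(names(config$clades)))) {
      stop("'clades' must be a named list of taxon-id vectors", call. = FALSE)
    }
    if (any(lengths(config$clades) == 0)) {
      stop("empty clade definition in config", call. = FALSE)
    }
  }
  if (is.null(config$weights)) config$weights <- list(subs = 1, ssr = 1)
  if (is.null(config$bootstrap)) {
    config$bootstrap <- list(reps = 100, seed = 1, model = "K2P")
  }
  if (is.null(config$bootstrap$model)) config$bootstrap$model <- "K2P"
  if (is.null(config$bootstrap$reps)) config$bootstrap$reps <- 100
  if (is.null(config$bootstrap$seed)) config$bootstrap$seed <- 1
  invisible(config)
}

.manifest_row <- function(stage, paths) {
  data.frame(stage = stage, output = unname(paths),
             md5 = unname(tools::md5sum(paths)),
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
             stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full screening pipeline
#'
#' Stages, in order: load or simulate per-locus alignments; per-locus
#' informativeness statistics; clade diagnostics (when clades are
#' configured); locus ranking; supermatrix concatenation and export; K2P
#' neighbor-joining with bootstrap support. All artifacts are written under
#' `config$outdir`; a manifest of output hashes makes runs comparable (two
#' runs with the same config and seed produce identical hashes for every
#' deterministic artifact).
#'
#' @param config see [validate_run_config()].
#' @return list with `manifest` (data.frame), `report`, `ranking`,
#'   `diagnostics` (or NULL), `supermatrix`, `tree`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  log <- function(...) message("[pipeline] ", sprintf(...))

  # stage 1: loci
  if (!is.null(config$simulate)) {
    log("simulating loci (seed %d)", as.integer(config$simulate$seed))
    sim <- make_marker_fixture(seed = as.integer(config$simulate$seed))
    alignments <- sim$alignments
  } else {
    files <- sort(list.files(config$loci_dir, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no FASTA files in ", config$loci_dir,
                                 call. = FALSE)
    alignments <- lapply(files, function(f) {
      locus_alignment(read_fasta(f),
                      locus_name = sub("\\.(fa|fasta)$", "", basename(f)))
    })
    names(alignments) <- vapply(alignments, `[[`, character(1), "locus_name")
    sim <- NULL
  }
  loci_dir <- file.path(outdir, "loci")
  dir.create(loci_dir, showWarnings = FALSE)
  loci_paths <- vapply(alignments, function(a) {
    write_fasta(aln_strings(a), file.path(loci_dir, paste0(a$locus_name,
                                                           ".fasta")))
  }, character(1))
  manifest[["loci"]] <- .manifest_row("loci", loci_paths)

  # stage 2: informativeness statistics
  thresholds <- if (is.null(config$ssr_thresholds)) ssr_thresholds() else {
    th <- unlist(config$ssr_thresholds)
    setNames(as.integer(th), names(th))
  }
  log("scoring %d loci", length(alignments))
  report <- do.call(rbind, lapply(alignments, informativeness_report,
                                  ssr_thresholds = thresholds))
  rownames(report) <- NULL
  p_stats <- .write_tsv(report, file.path(outdir, "informativeness.tsv"))
  manifest[["stats"]] <- .manifest_row("stats", p_stats)

  # stage 3: clade diagnostics
  diagnostics <- NULL
  if (!is.null(config$clades)) {
    taxa <- unique(unlist(lapply(alignments, aln_taxa)))
    for (cn in names(config$clades)) {
      missing <- setdiff(config$clades[[cn]], taxa)
      if (length(missing) > 0) {
        stop(sprintf("stage diagnose: clade '%s' references unknown taxa: %s",
                     cn, paste(missing, collapse = ", ")), call. = FALSE)
      }
    }
    diagnostics <- do.call(rbind, lapply(names(config$clades), function(cn) {
      part <- clade_partition(cn, config$clades[[cn]])
      tab <- clade_pis_table(alignments, part)
      tab$clade <- cn
      tab
    }))
    p_diag <- .write_tsv(diagnostics, file.path(outdir, "diagnostics.tsv"))
    manifest[["diagnose"]] <- .manifest_row("diagnose", p_diag)
  }

  # stage 4: ranking
  weights <- c(subs = as.numeric(config$weights$subs),
               ssr = as.numeric(config$weights$ssr))
  ranking <- rank_loci(report, weights = weights)
  p_rank <- .write_tsv(ranking, file.path(outdir, "ranking.tsv"))
  manifest[["rank"]] <- .manifest_row("rank", p_rank)

  # stage 5: supermatrix
  selected <- if (!is.null(config$top_k)) {
    utils::head(ranking$locus_name, config$top_k)
  } else ranking$locus_name
  log("concatenating %d selected loci", length(selected))
  sm <- concatenate_loci(alignments[sort(match(selected,
                                               names(alignments)))])
  p_sm <- export_for_inference(sm, file.path(outdir, "supermatrix"))
  manifest[["concat"]] <- .manifest_row("concat", p_sm)

  # stage 6: distance tree with bootstrap
  bs <- config$bootstrap
  log("NJ + %d bootstrap replicates (seed %d)", bs$reps, bs$seed)
  boot <- bootstrap_support(sm, model = bs$model, n_reps = bs$reps,
                            seed = bs$seed, outgroup = bs$outgroup)
  p_tree <- file.path(outdir, "tree.nwk")
  write_newick(boot$tree, p_tree)
  supp <- data.frame(split = names(boot$support),
                     support = unname(boot$support),
                     stringsAsFactors = FALSE)
  p_supp <- .write_tsv(supp, file.path(outdir, "support.tsv"))
  manifest[["tree"]] <- .manifest_row("tree", c(p_tree, p_supp))

  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  .write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  log("done: %d artifacts under %s", nrow(manifest), outdir)
  list(manifest = manifest, report = report, ranking = ranking,
       diagnostics = diagnostics, supermatrix = sm, tree = boot$tree,
       support = boot$support)
}
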