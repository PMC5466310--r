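# Orchestration: a validated run configuration, the report-bundle
# pipeline, and a thin command-line front end. All rounding happens in
# the report writers (2 d.p. percentages, 3 d.p. skews); every number
# in a rendered report is re-derivable from the emitted TSVs.

#' Validated pipeline configuration
#'
#' @param annotation Path to an annotation TSV (or `NULL`).
#' @param fasta Path to a genome FASTA (or `NULL`).
#' @param genbank Path to a GenBank flat file (or `NULL`).
#' @param mode `"table-only"` (annotation arithmetic only; never touches
#'   sequence-requiring stages) or `"sequence"`.
#' @param out_dir Output directory for the report bundle.
#' @param major_spacer_cutoff Spacer length counted as major (bp).
#' @param polyT_min Poly-T threshold for the control-region element.
#' @param ms_min_copies Microsatellite copy threshold.
#' @param phylo_model,phylo_reps,seed,outgroups Phylogeny stage
#'   settings (used by [run_phylo()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(annotation = NULL, fasta = NULL, genbank = NULL,
                       mode = c("table-only", "sequence"),
                       out_dir = "mitocharr_out",
                       major_spacer_cutoff = 10L, polyT_min = 10L,
                       ms_min_copies = 5, phylo_model = "K2P",
                       phylo_reps = 100L, seed = 1L, outgroups = NULL) {
  mode <- match.arg(mode)
  for (p in c(annotation, fasta, genbank))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  if (is.null(annotation) && is.null(fasta) && is.null(genbank))
    stop("no input given")
  if (mode == "sequence" && is.null(fasta) && is.null(genbank))
    stop("sequence mode needs a FASTA or GenBank input")
  structure(list(annotation = annotation, fasta = fasta, genbank = genbank,
                 mode = mode, out_dir = out_dir,
                 major_spacer_cutoff = as.integer(major_spacer_cutoff),
                 polyT_min = as.integer(polyT_min),
                 ms_min_copies = ms_min_copies, phylo_model = phylo_model,
                 phylo_reps = as.integer(phylo_reps),
                 seed = as.integer(seed), outgroups = outgroups),
            class = "run_config")
}

.load_genome <- function(config) {
  if (!is.null(config$genbank)) return(read_genbank(config$genbank))
  g <- read_annotation_table(config$annotation)
  if (config$mode == "sequence" && !is.null(config$fasta)) {
    fa <- read_fasta(config$fasta)
    g <- annotated_genome(fa$identifier, g$records,
                          length = nchar(fa$sequence),
                          sequence = fa$sequence)
  }
  g
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the characterization pipeline
#'
#' Produces a report bundle under `config$out_dir`: an annotation
#' report with consistency flags and the topology ledger/summary in
#' every mode; composition, codon/RSCU and motif reports additionally
#' in sequence mode. A `MANIFEST` lists the files written (and is
#' marked incomplete if a stage aborts); a `run.log` records every
#' stage with its parameters.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the loaded `genome` and the paths of
#'   the written reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  manifest <- character()
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  finish <- function(complete) {
    writeLines(c(if (!complete) "# INCOMPLETE RUN", manifest),
               file.path(config$out_dir, "MANIFEST"))
  }
  out <- list()
  stage <- "load"
  res <- tryCatch({
    genome <- .load_genome(config)
    say(stage, "loaded ", genome$identifier, " (", genome$length, " bp, ",
        length(genome$records), " features, mode=", config$mode, ")")

    stage <- "annotation"
    ann <- file.path(config$out_dir, "annotation_report.tsv")
    write_annotation_table(genome, ann)
    manifest <- c(manifest, ann)
    cons <- consistency_report(genome)
    cpath <- .write_tsv(cons, file.path(config$out_dir,
                                        "consistency_report.tsv"))
    manifest <- c(manifest, cpath)
    say(stage, nrow(cons), " printed-vs-computed inconsistencies")

    stage <- "topology"
    src <- if (any(!vapply(genome$records, function(r)
      is.na(r$intergenic_printed), logical(1)))) "printed" else "coordinates"
    led <- pair_ledger(genome, src)
    summ <- summarize_topology(led, config$major_spacer_cutoff)
    manifest <- c(manifest,
                  .write_tsv(led, file.path(config$out_dir,
                                            "topology_ledger.tsv")),
                  .write_tsv(data.frame(
                    metric = c("n_overlaps", "overlap_total_bp",
                               "overlap_max_bp", "n_spacers",
                               "spacer_total_bp", "spacer_max_bp",
                               "n_major_spacers"),
                    value = c(summ$n_overlaps, summ$overlap_total_bp,
                              summ$overlap_max_bp, summ$n_spacers,
                              summ$spacer_total_bp, summ$spacer_max_bp,
                              summ$n_major_spacers)),
                    file.path(config$out_dir, "topology_summary.tsv")))
    say(stage, summ$n_spacers, " spacers / ", summ$n_overlaps,
        " overlaps (source=", src, ")")
    out$topology <- summ

    if (config$mode == "sequence") {
      stage <- "composition"
      comp <- composition_report(list(genome))
      manifest <- c(manifest,
                    .write_tsv(comp, file.path(config$out_dir,
                                               "composition_report.tsv")))
      say(stage, nrow(comp), " panels")

      stage <- "codons"
      pcgs <- Filter(function(r) r$feature_class == "PCG", genome$records)
      cds <- lapply(pcgs, function(r) extract_feature_sequence(genome, r))
      usage <- rscu(codon_usage(cds))
      manifest <- c(manifest,
                    .write_tsv(codon_usage_report(usage),
                               file.path(config$out_dir, "codon_report.tsv")))
      say(stage, usage$n_codons, " codons, ",
          length(usage$missing), " missing")
      out$usage <- usage

      stage <- "motifs"
      hits <- spacer_motif_report(genome,
                                  min_spacer_len = config$major_spacer_cutoff,
                                  polyT_min = config$polyT_min,
                                  ms_min_copies = config$ms_min_copies)
      manifest <- c(manifest,
                    .write_tsv(hits, file.path(config$out_dir,
                                               "motif_hits.tsv")))
      say(stage, nrow(hits), " hits")
      out$motifs <- hits
    }
    out$genome <- genome
    TRUE
  }, error = function(e) {
    say(stage, "ERROR: ", conditionMessage(e))
    finish(FALSE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  finish(TRUE)
  out$manifest <- manifest
  invisible(out)
}

#' Phylogeny stage: supermatrix, distances, bootstrap NJ tree
#'
#' @param genomes List of [annotated_genome()] objects with aligned
#'   PCGs.
#' @param config A [run_config()] (phylogeny settings and output
#'   directory are used).
#' @return Invisibly, a list with `supermatrix`, `distances`, `tree`
#'   and the written paths.
#' @export
run_phylo <- function(genomes, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- build_supermatrix(genomes)
  d <- pairwise_distance(sm, config$phylo_model)
  tree <- bootstrap_support(sm, config$phylo_model, config$phylo_reps,
                            config$seed)
  if (!is.null(config$outgroups))
    tree <- root_with_outgroup(tree, config$outgroups)
  dpath <- file.path(config$out_dir, "distance_matrix.tsv")
  utils::write.table(round(d, 6), dpath, sep = "\t", quote = FALSE)
  tpath <- file.path(config$out_dir, "tree.nwk")
  write_newick(tree, tpath)
  invisible(list(supermatrix = sm, distances = d, tree = tree,
                 paths = c(dpath, tpath)))
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  opts
}

#' Command-line entry point
#'
#' Verbs: `characterize` (full bundle), `topology`, `codons`, `motifs`
#' (single-stage runs), `phylo` (simulated-clade tree when given
#' `--simulate`), `simulate` (emit a synthetic genome as FASTA +
#' GenBank + annotation + truth TSV). Common options: `--annotation`,
#' `--fasta`, `--genbank`, `--out DIR`, `--seed N`. Seeds are always
#' explicit; there is no wall-clock seeding.
#'
#' @param args Character vector of arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the result of the dispatched stage.
#' @export
mito_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: mito_cli <characterize|topology|codons|motifs|phylo|simulate> [--options]")
  verb <- args[1]
  opts <- .cli_opts(args[-1])
  out_dir <- if (!is.null(opts$out)) opts$out else "mitocharr_out"
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else 1L
  mode <- if (!is.null(opts$fasta) || !is.null(opts$genbank))
    "sequence" else "table-only"
  if (verb == "simulate") {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gen <- generate_mitogenome(genome_spec(seed = seed))
    write_fasta(gen$genome$identifier, gen$genome$sequence,
                file.path(out_dir, "genome.fasta"))
    write_genbank(gen$genome, file.path(out_dir, "genome.gb"))
    write_annotation_table(gen$genome, file.path(out_dir, "annotation.tsv"))
    .write_tsv(gen$truth, file.path(out_dir, "truth.tsv"))
    return(invisible(gen))
  }
  if (verb == "phylo") {
    if (is.null(opts$simulate))
      stop("phylo currently runs on simulated clades: pass --simulate")
    clade <- generate_clade(clade_spec(seed = seed))
    # bare config: the phylo stage needs no file inputs
    cfg <- structure(list(out_dir = out_dir, phylo_model = "K2P",
                          phylo_reps = if (!is.null(opts$reps))
                            as.integer(opts$reps) else 100L,
                          seed = seed, outgroups = NULL),
                     class = "run_config")
    return(invisible(run_phylo(clade$genomes, cfg)))
  }
  cfg <- run_config(annotation = opts$annotation, fasta = opts$fasta,
                    genbank = opts$genbank, mode = mode, out_dir = out_dir,
                    seed = seed)
  res <- run_pipeline(cfg)
  invisible(res)
}
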