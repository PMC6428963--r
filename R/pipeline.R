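#' Pipeline configuration
#'
#' Bundles every stage's parameters plus the global seed and output
#' directory.  Stage seeds are derived deterministically from the
#' global seed (small fixed offsets), so one integer reproduces the
#' whole run.  The configuration round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()], and every
#' run writes the fully resolved configuration it used.
#'
#' @param seed global integer seed.
#' @param outdir output directory.
#' @param genome,library,tags,pooling,reads,deconvolution,assembly
#'   named lists of overrides for [genome_params()],
#'   [bac_library_params()], [tag_params()],
#'   [build_pooling_design()] geometry, [read_sim_params()],
#'   [deconvolution_params()] and [assembly_params()].
#' @return object of class `wgp_pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = "wgp_run",
                            genome = list(),
                            library = list(),
                            tags = list(),
                            pooling = list(),
                            reads = list(),
                            deconvolution = list(),
                            assembly = list()) {
  genome <- modifyList(list(length_bp = 1e6, repeat_fraction = 0.85,
                            n_repeat_families = 20L,
                            family_length_range = c(500L, 5000L),
                            copy_mutation_rate = 0.02), genome)
  library <- modifyList(list(coverage_fold = 6.7, insert_mean_bp = 95000L,
                             insert_sd_bp = 0L, chimera_rate = 0), library)
  tags <- modifyList(list(tag_length_nt = 51L, read_length_nt = 100L),
                     tags)
  pooling <- modifyList(list(plate_rows = 16L, plate_cols = 24L,
                             box_rows = 8L, box_cols = 8L,
                             plates_per_row_pool = 2L,
                             plates_per_col_pool = 3L,
                             block_plates = 6L), pooling)
  reads <- modifyList(list(read_length_nt = 100L, depth_mean = 20,
                           error_rate = 0, fixed_depth = FALSE), reads)
  deconvolution <- modifyList(list(min_reads_per_pool = 2L), deconvolution)
  assembly <- modifyList(list(similarity_threshold = 0.75,
                              cutoff_schedule = c(1e-50, 1e-40, 1e-30,
                                                  1e-20, 1e-15, 1e-10,
                                                  1e-05, 1e-02, 1e-01),
                              end_clone_window = 3L), assembly)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 genome = genome, library = library, tags = tags,
                 pooling = pooling, reads = reads,
                 deconvolution = deconvolution, assembly = assembly),
            class = "wgp_pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `wgp_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(yaml::as.yaml(x), con, sep = "")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the whole WGP pipeline
#'
#' Executes simulate-genome -> sample-library -> digest -> pool ->
#' simulate-reads -> deconvolve -> assemble -> metrics, writing every
#' artifact under `config$outdir`: genome FASTA, repeat BED, clone and
#' pooling-design TSVs, pooled-read TSV, tag table and per-clone tag
#' TSVs, contig-size and contig-membership TSVs, an FPC-style project
#' file, metric reports (TSV and text), a log, and the resolved
#' configuration.  Fully reproducible: the same configuration and seed
#' give byte-identical tabular outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default `TRUE`).
#' @return invisibly, a list with the stage objects (`genome`,
#'   `clones`, `design`, `pooled`, `deconvolution`, `summary`,
#'   `assembly`, `metrics`) and `paths` (named artifact paths).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "wgp_pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage `%s` failed: %s", what, conditionMessage(e)))
  }
  p <- function(f) file.path(out, f)
  paths <- list()

  gp <- stage("simulate-genome", do.call(genome_params,
              c(config$genome, list(seed = config$seed))))
  genome <- stage("simulate-genome", generate_genome(gp))
  say("simulate-genome: %d bp, %d repeat copies (fraction %.3f)",
      genome$length_bp, nrow(genome$repeats),
      genome$realized_repeat_fraction)
  paths$genome_fasta <- write_genome_fasta(genome, p("genome.fasta"))
  paths$repeats_bed <- write_repeats_bed(genome, p("repeats.bed"))

  lp <- stage("sample-library", do.call(bac_library_params,
              c(config$library, list(seed = config$seed + 1L))))
  clones <- stage("sample-library", sample_bac_library(genome, lp))
  n_clones <- length(unique(clones$clone_id))
  say("sample-library: %d clones", n_clones)
  paths$clones_tsv <- write_clones_tsv(clones, p("clones.tsv"))

  tp <- stage("digest", do.call(tag_params, config$tags))
  tag_tab <- stage("digest", clone_wgp_tags(genome, clones, tp))
  say("digest: %d tag occurrences over %d clones", nrow(tag_tab),
      length(unique(tag_tab$clone_id)))

  design <- stage("pool", do.call(build_pooling_design,
                  c(list(clone_ids = sort(unique(clones$clone_id))),
                    config$pooling)))
  say("pool: %d pools in %d blocks", nrow(design$pools),
      length(unique(design$table$block)))
  paths$design_tsv <- write_design_tsv(design, p("pooling_design.tsv"))

  rp <- stage("simulate-reads", do.call(read_sim_params,
              c(config$reads, list(seed = config$seed + 2L))))
  occurrences <- split(tag_tab$tag_sequence, tag_tab$clone_id)
  pooled <- stage("simulate-reads",
                  simulate_pool_reads(occurrences, design, rp))
  say("simulate-reads: %d (pool, tag) groups, %d reads",
      nrow(pooled$reads), sum(pooled$reads$count))
  paths$pooled_reads_tsv <- write_pooled_reads_tsv(pooled,
                                                   p("pooled_reads.tsv"))

  dp <- stage("deconvolve", do.call(deconvolution_params,
              c(config$deconvolution,
                list(tag_length_nt = tp$tag_length_nt))))
  dec <- stage("deconvolve", deconvolve(pooled, design, dp))
  summ <- deconvolution_summary(dec, n_clones_in_library = n_clones)
  say("deconvolve: %d assignments, %.1f%% of reads deconvolvable",
      nrow(dec$assignments), summ$pct_deconvolvable)
  ttab <- tag_table(dec$assignments$tag_sequence)
  paths$tags_tsv <- write_tsv_file(ttab, p("tags.tsv"))
  fps <- fingerprints_from_assignments(dec)
  tag_id_of <- setNames(ttab$tag_id, ttab$tag_sequence)
  paths$clone_tags_tsv <- write_tsv_file(
    data.frame(clone_id = names(fps),
               tag_ids = vapply(fps, function(t)
                 paste(sort(tag_id_of[t]), collapse = ","), character(1))),
    p("clone_tags.tsv"))
  paths$deconvolution_summary_tsv <-
    write_tsv_file(metrics_table(summ), p("deconvolution_summary.tsv"))

  ap <- stage("assemble", do.call(assembly_params, config$assembly))
  if (length(fps) == 0L)
    stopf("pipeline stage `assemble` failed: no clone received any tag")
  assembly <- stage("assemble", assemble_clones(fps, ap))
  say("assemble: %d contigs, %d singletons, %d buried",
      length(assembly$contigs), length(assembly$singletons),
      nrow(assembly$burials))
  paths$fpc <- write_fpc(assembly, p("map.fpc"), name = "wgpmap-run")

  bur_per_parent <- table(assembly$burials$parent_clone)
  ctg_sizes <- data.frame(
    contig_id = vapply(assembly$contigs, `[[`, character(1), "contig_id"),
    n_bacs = vapply(assembly$contigs, function(ct)
      length(ct$members) +
        sum(bur_per_parent[ct$members], na.rm = TRUE), numeric(1)))
  paths$contig_sizes_tsv <- write_tsv_file(ctg_sizes, p("contig_sizes.tsv"))
  ccm <- clone_contig_map(assembly)
  in_ctg <- ccm[!startsWith(ccm, "singleton:")]
  members_tab <- data.frame(contig_id = unname(in_ctg),
                            clone_id = names(in_ctg))
  members_tab <- members_tab[order(members_tab$contig_id,
                                   members_tab$clone_id), ]
  paths$contig_members_tsv <- write_tsv_file(members_tab,
                                             p("contig_members.tsv"))

  anchors <- stage("metrics", genome_tag_anchors(genome, tp))
  mbp_per_cb <- mean_tag_distance(genome$length_bp, max(anchors, 1L)) / 1e6
  metrics <- stage("metrics", assembly_metrics(
    assembly, mbp_per_cb_unit = mbp_per_cb, library_size = n_clones,
    fpc_ready_count = length(fps)))
  say("metrics: %d contigs, %.3f Mbp mean contig span",
      metrics$n_contigs, ifelse(is.na(metrics$avg_contig_mbp), 0,
                                metrics$avg_contig_mbp))
  paths$metrics_tsv <- write_tsv_file(metrics_table(metrics),
                                      p("metrics.tsv"))
  con <- file(p("metrics.txt"), open = "wb")
  sink(con); print(summ); print(metrics); sink()
  close(con)
  paths$metrics_txt <- p("metrics.txt")

  paths$config_yaml <- write_pipeline_config(config, p("config_resolved.yaml"))
  con <- file(p("pipeline.log"), open = "wb")
  writeLines(log_lines, con, sep = "\n")
  close(con)
  paths$log <- p("pipeline.log")

  invisible(list(genome = genome, clones = clones, design = design,
                 pooled = pooled, deconvolution = dec, summary = summ,
                 assembly = assembly, metrics = metrics, paths = paths))
}
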