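# End-to-end orchestration: simulate -> call islands -> annotate -> profile
# -> overlap -> integrate, driven by one config, with a checksummed file
# manifest so reruns are verifiable.

#' Default pipeline configuration
#'
#' Nested list combining a [sim_config()] simulation block with the stage
#' parameters.  All randomness derives from the single root seed.
#'
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @param ... Overrides passed to [sim_config()].
#' @return List of class `run_config`.
#' @export
default_run_config <- function(out_dir, seed = 1, ...) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulation = sim_config(seed = seed, ...),
    caller = list(window = 200, gap = 200, p0 = 0.2, fdr = 1e-5,
                  shift = 0, control_mode = "each"),
    annotation = list(promoter_len = 2000),
    profiles = list(tss_flank = 5000, cpgi_flank = 5000,
                    body_flank = 3000, bin = 100, n_body_bins = 20),
    integration = list(fc_threshold = 2, upstream = 10000, pseudocount = 1)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any key present in the file overrides the [default_run_config()] value;
#' simulation parameters live under a `simulation:` block.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("config must set out_dir")
  cfg <- default_run_config(y$out_dir, seed = if (is.null(y$seed)) 1 else y$seed)
  if (!is.null(y$simulation))
    cfg$simulation <- do.call(sim_config,
                              c(y$simulation, list(seed = cfg$seed)))
  for (blk in c("caller", "annotation", "profiles", "integration"))
    if (!is.null(y[[blk]]))
      cfg[[blk]] <- utils::modifyList(cfg[[blk]], y[[blk]])
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Stages: (1) simulate genome, five tag samples (treatment ChIP, knockout
#' ChIP and input as controls, plus WT/KO samples of a promoter mark) and a
#' WT/KO expression table; (2) call islands for the treatment ChIP against
#' both controls and for each mark sample against input; (3) genome feature
#' partition and island feature distribution; (4) metaprofiles (TSS,
#' CpG-island centre, scaled gene body); (5) overlap accounting
#' (islands vs CpGI, islands vs mark); (6) direct-target integration.
#' Every output file is listed in `manifest.tsv` with its producing stage
#' and MD5 checksum; a rerun with the same config and seed reproduces
#' identical checksums.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return Manifest tibble (file, stage, md5), invisibly; the summary
#'   metrics are attached as attribute `"summary"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(path, stage) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)))
  }

  # -- stage: simulate -------------------------------------------------------
  sim <- config$simulation
  genome <- simulate_genome(sim)
  sizes <- genome$chrom_sizes
  add(write_chrom_sizes(sizes, file.path(out, "genome.chrom.sizes")),
      "simulate")
  add(write_gene_table(genome$genes, file.path(out, "genes.refflat")),
      "simulate")
  add(write_bed(genome$cpgi, file.path(out, "cpgi.bed")), "simulate")
  for (p in write_truth_set(genome$truth, out)) add(p, "simulate")

  # weakened-mark sample: same loci at half the enrichment above background
  mark_ko_enriched <- genome$truth$enriched
  mark_ko_enriched$fold <- 1 + (mark_ko_enriched$fold - 1) / 2

  samples <- list(
    chip_wt = simulate_chip_tags(genome, sim, "treatment", "chip_wt"),
    chip_ko = simulate_chip_tags(genome, sim, "control", "chip_ko"),
    input = simulate_chip_tags(genome, sim, "control", "input"),
    mark_wt = simulate_chip_tags(genome, sim, "treatment", "mark_wt"),
    mark_ko = simulate_chip_tags(genome, sim, "treatment", "mark_ko",
                                 enriched = mark_ko_enriched))
  for (nm in names(samples))
    add(write_tags(samples[[nm]], file.path(out, paste0(nm, ".tags.bed"))),
        "simulate")
  expr <- simulate_expression(genome, sim)
  add(write_tsv(expr, file.path(out, "expression.tsv")), "simulate")

  # -- stage: callislands ----------------------------------------------------
  params <- do.call(caller_params, config$caller)
  islands_wt <- call_islands(samples$chip_wt,
                             list(samples$chip_ko, samples$input),
                             params, sizes)
  # knockout ChIP treated as treatment vs input: the negative comparison
  islands_ko <- call_islands(samples$chip_ko, list(samples$input),
                             params, sizes)
  islands_mark_wt <- call_islands(samples$mark_wt, list(samples$input),
                                  params, sizes)
  islands_mark_ko <- call_islands(samples$mark_ko, list(samples$input),
                                  params, sizes)
  island_sets <- list(islands_chip_wt = islands_wt,
                      islands_chip_ko = islands_ko,
                      islands_mark_wt = islands_mark_wt,
                      islands_mark_ko = islands_mark_ko)
  for (nm in names(island_sets))
    add(write_bed(island_sets[[nm]], file.path(out, paste0(nm, ".bed"))),
        "callislands")
  wc <- count_window_tags(samples$chip_wt, sizes, params$window,
                          params$shift)
  add(write_bedgraph(wc, sizes, file.path(out, "chip_wt.windows.bedgraph")),
      "callislands")

  # -- stage: annotate -------------------------------------------------------
  partition <- build_partition(genome$genes, sizes,
                               config$annotation$promoter_len)
  add(write_partition(partition, file.path(out, "partition.bed")),
      "annotate")
  dist <- peak_feature_distribution(islands_wt, partition)
  add(write_tsv(dist, file.path(out, "island_feature_distribution.tsv")),
      "annotate")

  # -- stage: profile --------------------------------------------------------
  prof <- config$profiles
  tss_points <- tibble::tibble(chrom = genome$genes$chrom,
                               pos = tss(genome$genes),
                               strand = genome$genes$strand)
  spec_tss <- profile_spec("reference_point", flank = prof$tss_flank,
                           bin = prof$bin)
  p_tss_wt <- reference_point_profile(samples$mark_wt, tss_points,
                                      spec_tss, sizes)
  p_tss_ko <- reference_point_profile(samples$mark_ko, tss_points,
                                      spec_tss, sizes)
  add(write_profile(p_tss_wt, file.path(out, "profile_tss_mark_wt.tsv")),
      "profile")
  add(write_profile(p_tss_ko, file.path(out, "profile_tss_mark_ko.tsv")),
      "profile")
  if (nrow(genome$cpgi)) {
    cpgi_points <- tibble::tibble(
      chrom = genome$cpgi$chrom,
      pos = (genome$cpgi$start + genome$cpgi$end) %/% 2L,
      strand = "*")
    p_cpgi <- reference_point_profile(
      samples$chip_wt, cpgi_points,
      profile_spec("reference_point", flank = prof$cpgi_flank,
                   bin = prof$bin), sizes)
    add(write_profile(p_cpgi, file.path(out, "profile_cpgi_chip_wt.tsv")),
        "profile")
  }
  p_body <- gene_body_profile(
    samples$chip_wt, genome$genes,
    profile_spec("scaled_gene_body", flank = prof$body_flank,
                 bin = prof$bin, n_body_bins = prof$n_body_bins), sizes)
  add(write_profile(p_body, file.path(out, "profile_genebody_chip_wt.tsv")),
      "profile")

  # -- stage: overlap --------------------------------------------------------
  ov_cpgi <- overlap_query(islands_wt, genome$cpgi)
  ov_mark <- overlap_query(islands_wt, islands_mark_wt)
  ov_tbl <- tibble::tibble(
    comparison = c("islands_vs_cpgi", "islands_vs_mark_wt"),
    n_a = c(ov_cpgi$n_a, ov_mark$n_a),
    n_b = c(ov_cpgi$n_b, ov_mark$n_b),
    n_a_overlap = c(ov_cpgi$n_a_overlap, ov_mark$n_a_overlap),
    n_b_overlap = c(ov_cpgi$n_b_overlap, ov_mark$n_b_overlap),
    n_shared_regions = c(ov_cpgi$n_shared_regions,
                         ov_mark$n_shared_regions),
    frac_a = c(ov_cpgi$frac_a, ov_mark$frac_a),
    frac_b = c(ov_cpgi$frac_b, ov_mark$frac_b))
  add(write_tsv(ov_tbl, file.path(out, "overlap_report.tsv")), "overlap")
  vr <- venn_regions(islands_wt, islands_mark_wt)
  for (part in c("a_only", "shared", "b_only"))
    add(write_bed(vr[[part]],
                  file.path(out, paste0("venn_islands_mark_", part, ".bed"))),
        "overlap")

  # -- stage: integrate ------------------------------------------------------
  integ <- config$integration
  dt <- call_direct_targets(islands_wt, genome$genes, expr, sizes,
                            fc_threshold = integ$fc_threshold,
                            upstream = integ$upstream,
                            pseudocount = integ$pseudocount)
  add(write_tsv(dt$records, file.path(out, "direct_targets.tsv")),
      "integrate")
  add(write_tsv(dt$summary, file.path(out, "direct_target_summary.tsv")),
      "integrate")
  scatter <- fold_changes(expr, integ$pseudocount)
  add(write_tsv(scatter[, c("gene_id", "cpm_WT", "cpm_KO", "log2fc")],
                file.path(out, "expression_scatter.tsv")), "integrate")

  # -- summary + manifest ----------------------------------------------------
  rec <- island_recovery_stats(islands_wt, genome$truth$enriched)
  summary <- tibble::tibble(
    metric = c("n_islands_chip_wt", "n_islands_chip_ko",
               "n_islands_mark_wt", "n_islands_mark_ko",
               "island_recall", "island_precision",
               "frac_islands_on_cpgi", "n_bound_genes",
               "n_direct_targets", "fraction_down"),
    value = c(nrow(islands_wt), nrow(islands_ko),
              nrow(islands_mark_wt), nrow(islands_mark_ko),
              rec$recall, rec$precision, ov_cpgi$frac_a,
              dt$summary$n_bound, dt$summary$n_bound_and_changed,
              dt$summary$fraction_down))
  add(write_tsv(summary, file.path(out, "run_summary.tsv")), "summary")
  cfg_path <- file.path(out, "run_config.yaml")
  yaml::write_yaml(list(seed = config$seed,
                        simulation = unclass(config$simulation),
                        caller = config$caller,
                        annotation = config$annotation,
                        profiles = config$profiles,
                        integration = config$integration), cfg_path)
  add(cfg_path, "config")

  manifest <- dplyr::bind_rows(manifest)
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  attr(manifest, "summary") <- summary
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' Re-reads the stage outputs under `run_dir` and tabulates island counts,
#' the feature distribution against its genome baseline, overlap fractions
#' and the direct-target summary.  Stages without outputs are listed as not
#' run.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
report_summary <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.tsv")
  lines <- character()
  say <- function(...) lines <<- c(lines, sprintf(...))
  if (!file.exists(man_path)) {
    say("no stages run in %s", run_dir)
    writeLines(lines)
    return(invisible(lines))
  }
  man <- utils::read.delim(man_path)
  say("pipeline run: %s (%d files)", run_dir, nrow(man))
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) utils::read.delim(p) else NULL
  }
  smry <- rd("run_summary.tsv")
  if (is.null(smry)) say("summary: not run")
  else for (i in seq_len(nrow(smry)))
    say("  %-22s %s", smry$metric[i], format(smry$value[i], digits = 4))
  dist <- rd("island_feature_distribution.tsv")
  if (is.null(dist)) say("annotate: not run")
  else {
    say("island feature distribution (vs genome baseline):")
    for (i in seq_len(nrow(dist)))
      say("  %-10s %5d islands  %5.1f%%  (genome %5.1f%%)", dist$label[i],
          dist$peak_count[i], 100 * dist$peak_fraction[i],
          100 * dist$genome_fraction[i])
  }
  ov <- rd("overlap_report.tsv")
  if (is.null(ov)) say("overlap: not run")
  else for (i in seq_len(nrow(ov)))
    say("overlap %-20s A-with-B %d/%d (%.1f%%), shared regions %d",
        ov$comparison[i], ov$n_a_overlap[i], ov$n_a[i],
        100 * ov$frac_a[i], ov$n_shared_regions[i])
  writeLines(lines)
  invisible(lines)
}
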