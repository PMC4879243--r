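# Synthetic genomes, tag sets and expression tables with planted truth.
#
# The generator emulates the data layout of a ChIP-seq + RNA-seq study of a
# promoter-binding factor in a knockout background: uniquely mapped 50-bp
# tags as a uniform Poisson background with planted enriched islands at
# designated promoters, plus WT/KO negative-binomial count pairs with
# planted fold changes.  Everything is deterministic given the seed.

#' Simulation configuration
#'
#' Defaults define the desk-scale study conditions used throughout the test
#' suite: 2 chromosomes x 5 Mb, 500 genes, 200 CpG islands, 2e5 tags per
#' sample, 50 planted 1-kb islands at 10x enrichment, and 40 planted direct
#' targets (85% down-regulated) among the genes.  The four designated target
#' genes carry 6.9-, 2.8-, 4.2- and 3.7-fold KO reductions; the remaining
#' planted fold magnitudes are drawn log-uniform from [2.8, 6.9], the span of
#' those designated values.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Number of non-overlapping genes to place.
#' @param gene_length Length range `c(min, max)` in bp.
#' @param promoter_len Promoter extent upstream of the TSS (bp).
#' @param n_cpgi Number of CpG islands.
#' @param cpgi_width CpG island width (bp).
#' @param cpgi_promoter_frac Fraction of CpG islands centred on gene TSSs.
#' @param depth Expected number of tags per sample (library size).
#' @param tag_length Read length metadata (bp).
#' @param n_direct_targets Genes planted as direct targets (bound + changed).
#' @param n_bound_unchanged Genes planted with an island but no expression
#'   change.
#' @param frac_down Fraction of direct targets that are down-regulated.
#' @param enrichment_fold Tag-rate fold enrichment inside planted islands.
#' @param enrichment_width Width of planted islands (bp).
#' @param designated_folds Named numeric: KO fold reductions planted at four
#'   designated down-regulated genes.
#' @param fold_range Range for the remaining planted fold magnitudes.
#' @param expression_mean Baseline negative-binomial mean per gene.
#' @param dispersion Negative-binomial dispersion phi (Var = mu + phi mu^2).
#' @param seed Root seed; all generators derive determinism from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 5e6, n_genes = 500,
                       gene_length = c(2000, 20000), promoter_len = 2000,
                       n_cpgi = 200, cpgi_width = 1000,
                       cpgi_promoter_frac = 0.5,
                       depth = 2e5, tag_length = 50,
                       n_direct_targets = 40, n_bound_unchanged = 10,
                       frac_down = 0.85,
                       enrichment_fold = 10, enrichment_width = 1000,
                       designated_folds = c(tCd8a = 6.9, tZap70 = 2.8,
                                            tLck = 4.2, tRorc = 3.7),
                       fold_range = c(2.8, 6.9),
                       expression_mean = 1000, dispersion = 0.05,
                       seed = 1) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              promoter_len = as.integer(promoter_len),
              n_cpgi = as.integer(n_cpgi),
              cpgi_width = as.integer(cpgi_width),
              cpgi_promoter_frac = cpgi_promoter_frac,
              depth = depth, tag_length = as.integer(tag_length),
              n_direct_targets = as.integer(n_direct_targets),
              n_bound_unchanged = as.integer(n_bound_unchanged),
              frac_down = frac_down,
              enrichment_fold = enrichment_fold,
              enrichment_width = as.integer(enrichment_width),
              designated_folds = designated_folds,
              fold_range = fold_range,
              expression_mean = expression_mean,
              dispersion = dispersion,
              seed = as.integer(seed))
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length >= 1, cfg$n_genes >= 0,
            length(cfg$gene_length) == 2,
            cfg$gene_length[1] <= cfg$gene_length[2],
            cfg$promoter_len >= 0, cfg$n_cpgi >= 0, cfg$cpgi_width >= 1,
            cfg$cpgi_promoter_frac >= 0, cfg$cpgi_promoter_frac <= 1,
            cfg$depth > 0, cfg$enrichment_fold >= 1, cfg$dispersion > 0,
            cfg$frac_down >= 0, cfg$frac_down <= 1,
            cfg$n_direct_targets + cfg$n_bound_unchanged <= max(cfg$n_genes, 0))
  if (any(cfg$designated_folds <= 0)) stop("fold changes must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic sub-seed for a named stage, kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% .Machine$integer.max)
}

#' Simulate a toy genome with planted truth
#'
#' Places non-overlapping genes with random strands and exon structure,
#' CpG islands (a configurable fraction centred on gene TSSs), planted
#' enriched islands at the promoters of designated genes, and planted
#' expression fold changes.  Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `chrom_sizes`, `genes`, `cpgi` (interval
#'   tibble) and `truth` (see Details).  `truth` holds `enriched` (planted
#'   island tibble with fold and owning gene), `fold_changes`
#'   (gene_id, fold = WT/KO mean ratio, log2fc_true = log2(KO/WT)), and
#'   `direct_targets` (character vector of planted direct-target gene ids).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  sizes <- chrom_sizes(stats::setNames(
    rep(config$chrom_length, config$n_chroms),
    paste0("chr", seq_len(config$n_chroms))))

  genes <- place_genes(config, sizes)

  # CpG islands: a fraction centred on random TSSs, the rest uniform.
  n_prom <- round(config$cpgi_promoter_frac * config$n_cpgi)
  n_prom <- min(n_prom, nrow(genes))
  cpgi_parts <- list()
  if (n_prom > 0) {
    at <- sample(nrow(genes), n_prom)
    centre <- tss(genes)[at]
    cpgi_parts$prom <- tibble::tibble(
      chrom = genes$chrom[at],
      start = centre - config$cpgi_width %/% 2L,
      end = centre - config$cpgi_width %/% 2L + config$cpgi_width)
  }
  n_rand <- config$n_cpgi - n_prom
  if (n_rand > 0) {
    ch <- sample(names(sizes), n_rand, replace = TRUE)
    st <- floor(runif(n_rand) * (sizes[ch] - config$cpgi_width))
    cpgi_parts$rand <- tibble::tibble(chrom = ch, start = as.integer(st),
                                      end = as.integer(st) + config$cpgi_width)
  }
  cpgi <- dplyr::bind_rows(cpgi_parts)
  if (!nrow(cpgi))
    cpgi <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer())
  cpgi <- clip_intervals(cpgi, sizes)
  cpgi <- cpgi[order(cpgi$chrom, cpgi$start), , drop = FALSE]
  cpgi$name <- sprintf("cpgi%04d", seq_len(nrow(cpgi)))
  cpgi$strand <- "*"

  truth <- plant_truth(config, sizes, genes)
  list(chrom_sizes = sizes, genes = genes, cpgi = cpgi, truth = truth)
}

# Non-overlapping gene placement: genes are split across chromosomes; on each
# chromosome sampled lengths must fit with room for inter-gene gaps, which
# are drawn from a uniform partition of the leftover space.
place_genes <- function(config, sizes) {
  n <- config$n_genes
  empty <- tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), exon_starts = list(),
                          exon_ends = list())
  if (n == 0) return(empty)
  chrom_of <- rep(names(sizes), length.out = n)
  lens <- sample(seq(config$gene_length[1], config$gene_length[2]), n,
                 replace = TRUE)
  parts <- lapply(names(sizes), function(ch) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) return(NULL)
    L <- as.numeric(sizes[[ch]])
    l <- lens[idx]
    free <- L - sum(as.numeric(l))
    if (free < length(l) + 1)
      stop("cannot place ", length(l), " genes totalling ", sum(l),
           " bp on a ", L, "-bp chromosome; use a larger genome")
    cuts <- sort(runif(length(l)))
    gaps <- floor(diff(c(0, cuts, 1)) * free)[seq_along(l)]
    starts <- cumsum(gaps) + cumsum(c(0, l[-length(l)]))
    tibble::tibble(chrom = ch, start = as.integer(starts),
                   end = as.integer(starts + l))
  })
  g <- dplyr::bind_rows(parts)
  g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
  g$gene_id <- sprintf("g%04d", seq_len(nrow(g)))
  ex <- lapply(seq_len(nrow(g)), function(i)
    make_exons(g$start[i], g$end[i]))
  g$exon_starts <- lapply(ex, `[[`, "starts")
  g$exon_ends <- lapply(ex, `[[`, "ends")
  validate_genes(g[, c("gene_id", "chrom", "strand", "start", "end",
                       "exon_starts", "exon_ends")])
}

# Random exon structure: 2-6 compact blocks (roughly 100-300 bp, like real
# coding exons) separated by introns that take up the rest of the span, so
# the genome-wide exon fraction stays realistically small.  Blocks are
# flush with the gene span.
make_exons <- function(start, end) {
  len <- end - start
  k <- sample(2:6, 1)
  w <- sample(100:300, k, replace = TRUE)
  if (sum(w) + (k - 1) > len) return(list(starts = start, ends = end))
  total_gap <- len - sum(w)
  cuts <- if (k > 2) sort(runif(k - 2)) else numeric()
  gaps <- 1 + floor(diff(c(0, cuts, 1)) * (total_gap - (k - 1)))
  gaps[1] <- gaps[1] + (total_gap - sum(gaps))
  starts <- start + cumsum(c(0, w[-k] + gaps))
  list(starts = as.integer(starts), ends = as.integer(starts + w))
}

# Plant islands at promoters of target + bound-unchanged genes, and fold
# changes at target genes (frac_down of them down-regulated).
plant_truth <- function(config, sizes, genes) {
  nt <- config$n_direct_targets; nb <- config$n_bound_unchanged
  empty_fc <- tibble::tibble(gene_id = character(), fold = numeric(),
                             log2fc_true = numeric(), direction = character())
  if (nt + nb == 0 || nrow(genes) == 0)
    return(list(enriched = tibble::tibble(chrom = character(),
                                          start = integer(), end = integer(),
                                          fold = numeric(),
                                          gene_id = character()),
                fold_changes = empty_fc, direct_targets = character()))
  picked <- sample(nrow(genes), nt + nb)
  target_idx <- picked[seq_len(nt)]
  bound_idx <- picked[-seq_len(nt)]

  n_down <- round(config$frac_down * nt)
  n_desig <- min(length(config$designated_folds), n_down)
  extra_down <- n_down - n_desig
  f_down <- c(unname(config$designated_folds)[seq_len(n_desig)],
              exp(runif(extra_down, log(config$fold_range[1]),
                        log(config$fold_range[2]))))
  f_up <- 1 / exp(runif(nt - n_down, log(config$fold_range[1]),
                        log(config$fold_range[2])))
  folds <- c(f_down, f_up)
  direction <- rep(c("down", "up"), c(n_down, nt - n_down))

  all_idx <- c(target_idx, bound_idx)
  centre <- tss(genes)[all_idx]
  w <- config$enrichment_width
  enriched <- tibble::tibble(chrom = genes$chrom[all_idx],
                             start = as.integer(centre - w %/% 2L),
                             end = as.integer(centre - w %/% 2L + w),
                             fold = config$enrichment_fold,
                             gene_id = genes$gene_id[all_idx])
  # keep planted width intact at chromosome edges by shifting, then clip
  enriched$start <- pmax(enriched$start, 0L)
  enriched$end <- pmin(enriched$end, unname(sizes[enriched$chrom]))

  fold_changes <- tibble::tibble(gene_id = genes$gene_id[target_idx],
                                 fold = folds,
                                 log2fc_true = -log2(folds),
                                 direction = direction)
  list(enriched = enriched, fold_changes = fold_changes,
       direct_targets = genes$gene_id[target_idx])
}

#' Simulate a ChIP tag set
#'
#' Tag 5' positions are drawn as a heterogeneous Poisson process: rate
#' `lambda_bg = depth / genome_length` everywhere, raised to
#' `fold * lambda_bg` inside planted enriched intervals for treatment
#' samples.  Control samples are pure background.  Strands are assigned at
#' random.  The realized library size is recorded in the returned
#' `tag_set`.
#'
#' @param genome Output of [simulate_genome()].
#' @param config The [sim_config()].
#' @param sample_role "treatment" (planted enrichment applies) or "control".
#' @param sample_id Sample name; also salts the derived seed so each sample
#'   is an independent draw.
#' @param enriched Optional interval tibble with a `fold` column overriding
#'   `genome$truth$enriched` (used for, e.g., a second mark or a weakened
#'   knockout sample).
#' @return A `tag_set`.
#' @export
simulate_chip_tags <- function(genome, config,
                               sample_role = c("treatment", "control"),
                               sample_id = sample_role,
                               enriched = NULL) {
  sample_role <- match.arg(sample_role)
  stopifnot(inherits(config, "sim_config"))
  if (sample_role == "treatment" && is.null(enriched))
    enriched <- genome$truth$enriched
  set.seed(derive_seed(config$seed, paste0("tags:", sample_id)))
  sizes <- genome$chrom_sizes
  genome_len <- sum(as.numeric(sizes))
  lambda_bg <- config$depth / genome_len

  parts <- lapply(names(sizes), function(ch) {
    L <- as.numeric(sizes[[ch]])
    n_bg <- stats::rpois(1, lambda_bg * L)
    pos <- floor(runif(n_bg) * L)
    if (sample_role == "treatment" && !is.null(enriched)) {
      e <- enriched[enriched$chrom == ch, , drop = FALSE]
      if (nrow(e)) {
        extra <- stats::rpois(nrow(e), (e$fold - 1) * lambda_bg *
                                (e$end - e$start))
        pos2 <- unlist(lapply(seq_len(nrow(e)), function(i)
          e$start[i] + floor(runif(extra[i]) * (e$end[i] - e$start[i]))))
        pos <- c(pos, pos2)
      }
    }
    tibble::tibble(chrom = ch, pos = as.integer(pos))
  })
  tags <- dplyr::bind_rows(parts)
  tags$strand <- sample(c("+", "-"), nrow(tags), replace = TRUE)
  tags <- tags[order(tags$chrom, tags$pos), , drop = FALSE]
  tag_set(sample_id, tags$chrom, tags$pos, tags$strand,
          tag_length = config$tag_length, chrom_sizes = sizes)
}

#' Simulate a WT/KO expression count table
#'
#' Per-gene counts are negative-binomial with mean `expression_mean` (WT)
#' and `expression_mean / fold` (KO) for genes carrying a planted fold
#' change, and common dispersion phi (`Var = mu + phi * mu^2`).  Genes
#' without a planted fold have fold 1.
#'
#' @param genome Output of [simulate_genome()].
#' @param config The [sim_config()].
#' @param fold_changes Optional override tibble (gene_id, fold); defaults to
#'   the planted `genome$truth$fold_changes`.
#' @return Tibble (gene_id, count_WT, count_KO).
#' @export
simulate_expression <- function(genome, config, fold_changes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(fold_changes)) fold_changes <- genome$truth$fold_changes
  if (nrow(fold_changes) && any(fold_changes$fold <= 0))
    stop("fold changes must be > 0")
  set.seed(derive_seed(config$seed, "expression"))
  genes <- genome$genes
  fold <- rep(1, nrow(genes))
  idx <- match(fold_changes$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("fold-change map names unknown gene(s)")
  fold[idx] <- fold_changes$fold
  mu <- config$expression_mean
  size <- 1 / config$dispersion
  tibble::tibble(gene_id = genes$gene_id,
                 count_WT = stats::rnbinom(nrow(genes), mu = mu, size = size),
                 count_KO = stats::rnbinom(nrow(genes), mu = mu / fold,
                                           size = size))
}

#' Write the planted truth set as plain TSV files
#'
#' @param truth `genome$truth` from [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "truth_enriched.tsv")
  p2 <- file.path(dir, "truth_fold_changes.tsv")
  p3 <- file.path(dir, "truth_direct_targets.tsv")
  utils::write.table(truth$enriched, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$fold_changes, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = truth$direct_targets), p3,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
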