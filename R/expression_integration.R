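# WT/KO expression normalization, fold changes, and the direct-target rule
# combining binding (a peak within the extended gene body) with expression
# change (at least the fold threshold in either direction).

#' Depth-normalize a WT/KO count table (counts per million)
#'
#' @param expr Tibble (gene_id, count_WT, count_KO).
#' @param lib_sizes Optional numeric `c(WT, KO)` library sizes; default
#'   column sums.
#' @return `expr` with added `cpm_WT`, `cpm_KO`; library sizes in the
#'   `lib_sizes` attribute.
#' @export
normalize_counts <- function(expr, lib_sizes = NULL) {
  stopifnot(all(c("gene_id", "count_WT", "count_KO") %in% names(expr)))
  if (any(expr$count_WT < 0) || any(expr$count_KO < 0))
    stop("counts must be >= 0")
  if (is.null(lib_sizes))
    lib_sizes <- c(WT = sum(expr$count_WT), KO = sum(expr$count_KO))
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  expr$cpm_WT <- expr$count_WT / lib_sizes[[1]] * 1e6
  expr$cpm_KO <- expr$count_KO / lib_sizes[[2]] * 1e6
  attr(expr, "lib_sizes") <- lib_sizes
  expr
}

#' Per-gene fold changes between WT and knockout
#'
#' Two orientations are reported.  `fc = (cpm_WT + c) / (cpm_KO + c)` is the
#' WT-over-KO ratio, so an n-fold reduction in the knockout reads as
#' `fc = n`.  `log2fc = log2(KO/WT) = -log2(fc)` is the conventional
#' differential-expression orientation: down-regulation in the knockout is
#' negative.
#'
#' @param expr Normalized table from [normalize_counts()] (un-normalized
#'   tables are normalized first).
#' @param pseudocount Pseudocount c added to both normalized values
#'   (default 1); must be > 0 if any normalized value is 0.
#' @return `expr` with added `fc` and `log2fc`.
#' @export
fold_changes <- function(expr, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  if (!all(c("cpm_WT", "cpm_KO") %in% names(expr)))
    expr <- normalize_counts(expr)
  if (pseudocount == 0 && any(expr$cpm_WT == 0 | expr$cpm_KO == 0))
    stop("zero normalized value requires a pseudocount > 0")
  expr$fc <- (expr$cpm_WT + pseudocount) / (expr$cpm_KO + pseudocount)
  expr$log2fc <- -log2(expr$fc)
  expr
}

#' Extended gene body
#'
#' The gene span plus a strand-relative upstream extension: for a "+" gene
#' `[start - upstream, end)`, for a "-" gene `[start, end + upstream)`,
#' clipped to the chromosome.
#'
#' @param genes Gene tibble.
#' @param upstream Upstream extension in bp (default 10000).
#' @param chrom_sizes Named chromosome lengths.
#' @return Interval tibble (gene_id, chrom, start, end, strand).
#' @export
extended_gene_body <- function(genes, upstream = 10000, chrom_sizes) {
  stopifnot(upstream >= 0)
  ext <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$start - as.integer(upstream),
                   genes$start),
    end = ifelse(genes$strand == "+", genes$end,
                 genes$end + as.integer(upstream)),
    strand = genes$strand)
  clip_intervals(ext, chrom_sizes)
}

#' Call direct target genes from binding and expression change
#'
#' A gene is *bound* when any peak overlaps its extended gene body
#' (`upstream` bp upstream of the TSS plus the gene body) by at least one
#' base.  Expression classes use `log2fc` (KO vs WT): down when
#' `log2fc <= -log2(fc_threshold)`, up when `log2fc >= log2(fc_threshold)`,
#' else unchanged.  Direct targets are bound genes whose class is not
#' unchanged.
#'
#' @param peaks Interval tibble of called islands.
#' @param genes Gene tibble.
#' @param expr Expression tibble (gene_id, count_WT, count_KO).
#' @param chrom_sizes Named chromosome lengths.
#' @param fc_threshold Fold-change threshold (> 1; default 2, i.e. the
#'   "over twofold" rule).
#' @param upstream Upstream extension in bp (default 10000).
#' @param pseudocount Pseudocount for [fold_changes()] (default 1).
#' @return List: `records` (gene_id, bound, fc, log2fc, class,
#'   direct_target), `summary` (n_genes, n_bound, n_bound_and_changed,
#'   n_down, n_up, fraction_down), and `skipped` (expression gene ids
#'   missing from the annotation).
#' @export
call_direct_targets <- function(peaks, genes, expr, chrom_sizes,
                                fc_threshold = 2, upstream = 10000,
                                pseudocount = 1) {
  stopifnot(fc_threshold > 1)
  ext <- extended_gene_body(genes, upstream, chrom_sizes)
  bound_ids <- character()
  if (nrow(peaks)) {
    for (ch in intersect(unique(ext$chrom), unique(peaks$chrom))) {
      ei <- which(ext$chrom == ch)
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(ext$start[ei] + 1L, ext$end[ei]),
        IRanges::IRanges(pk$start + 1L, pk$end))
      bound_ids <- c(bound_ids, ext$gene_id[ei][hit])
    }
  }
  skipped <- setdiff(expr$gene_id, genes$gene_id)
  expr <- expr[expr$gene_id %in% genes$gene_id, , drop = FALSE]
  expr <- fold_changes(expr, pseudocount)
  lfc_cut <- log2(fc_threshold)
  records <- tibble::tibble(
    gene_id = expr$gene_id,
    bound = expr$gene_id %in% bound_ids,
    fc = expr$fc,
    log2fc = expr$log2fc,
    class = dplyr::case_when(expr$log2fc <= -lfc_cut ~ "down",
                             expr$log2fc >= lfc_cut ~ "up",
                             TRUE ~ "unchanged"))
  records$direct_target <- records$bound & records$class != "unchanged"
  changed_bound <- records[records$direct_target, , drop = FALSE]
  summary <- tibble::tibble(
    n_genes = nrow(records),
    n_bound = sum(records$bound),
    n_bound_and_changed = nrow(changed_bound),
    n_down = sum(changed_bound$class == "down"),
    n_up = sum(changed_bound$class == "up"),
    fraction_down = if (nrow(changed_bound))
      mean(changed_bound$class == "down") else NA_real_)
  list(records = records, summary = summary, skipped = skipped)
}
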