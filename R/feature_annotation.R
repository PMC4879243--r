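# Promoter/exon/intron/intergenic genome partition and peak classification.
#
# Every base gets exactly one label, resolved by the fixed precedence
# promoter > exon > intron > intergenic; peaks are classified by the
# highest-precedence label they overlap by at least one base.

FEATURE_LEVELS <- c("promoter", "exon", "intron", "intergenic")

#' Partition the genome into promoter/exon/intron/intergenic
#'
#' Promoters are the strand-relative `[TSS - promoter_len, TSS)` windows
#' (for "-" genes this lies to the right of the gene span), clipped to the
#' chromosome.  Exons are the union of exon blocks; introns the remainder of
#' gene spans.  Collisions (including between overlapping genes) are
#' resolved base-by-base with precedence promoter > exon > intron;
#' everything else is intergenic.  The labeled intervals tile each
#' chromosome exactly.
#'
#' @param genes Gene tibble.
#' @param chrom_sizes Named chromosome lengths.
#' @param promoter_len Promoter extent upstream of the TSS in bp
#'   (default 2000).
#' @return Object of class `feature_partition`: tibble (chrom, start, end,
#'   label) plus a `summary` attribute with per-label bp and genome
#'   fraction.
#' @export
build_partition <- function(genes, chrom_sizes, promoter_len = 2000) {
  stopifnot(promoter_len >= 0)
  if (nrow(genes)) {
    unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("gene(s) on unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
  }
  t0 <- tss(genes)
  prom <- tibble::tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", t0 - promoter_len, t0 + 1L),
    end = ifelse(genes$strand == "+", t0, t0 + 1L + promoter_len))
  prom <- prom[prom$start < prom$end, , drop = FALSE]
  if (nrow(prom)) prom <- clip_intervals(prom, chrom_sizes)
  exon <- tibble::tibble(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = as.integer(unlist(genes$exon_starts, use.names = FALSE)),
    end = as.integer(unlist(genes$exon_ends, use.names = FALSE)))
  body <- genes[, c("chrom", "start", "end")]

  chroms <- names(chrom_sizes)
  prom_ir <- as_iranges_by_chrom(prom, chroms)
  exon_ir <- as_iranges_by_chrom(exon, chroms)
  body_ir <- as_iranges_by_chrom(body, chroms)

  parts <- lapply(chroms, function(ch) {
    all_ir <- IRanges::IRanges(1L, chrom_sizes[[ch]])
    p <- IRanges::reduce(prom_ir[[ch]])
    e <- IRanges::setdiff(IRanges::reduce(exon_ir[[ch]]), p)
    i <- IRanges::setdiff(
      IRanges::setdiff(IRanges::reduce(body_ir[[ch]]), p),
      IRanges::reduce(exon_ir[[ch]]))
    g <- IRanges::setdiff(IRanges::setdiff(IRanges::setdiff(all_ir, p), e), i)
    lab_tbl <- function(ir, lab)
      tibble::tibble(chrom = rep(ch, length(ir)),
                     start = IRanges::start(ir) - 1L,
                     end = IRanges::end(ir), label = lab)
    dplyr::bind_rows(lab_tbl(p, "promoter"), lab_tbl(e, "exon"),
                     lab_tbl(i, "intron"), lab_tbl(g, "intergenic"))
  })
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  bp <- unname(vapply(FEATURE_LEVELS, function(l)
    sum(as.numeric(out$end[out$label == l] - out$start[out$label == l])), 0))
  total <- sum(as.numeric(chrom_sizes))
  summary <- tibble::tibble(label = FEATURE_LEVELS, bp = bp,
                            genome_fraction = bp / total)
  structure(out, summary = summary, promoter_len = promoter_len,
            genome_length = total,
            class = c("feature_partition", class(out)))
}

#' Classify peaks against a feature partition
#'
#' Each peak gets the highest-precedence label
#' (promoter > exon > intron > intergenic) of any feature it overlaps by at
#' least one base.
#'
#' @param peaks Interval tibble.
#' @param partition A [build_partition()] result.
#' @return Factor of labels, one per peak.
#' @export
classify_peaks <- function(peaks, partition) {
  lab <- rep(NA_character_, nrow(peaks))
  if (!nrow(peaks))
    return(factor(lab, levels = FEATURE_LEVELS))
  for (feature in FEATURE_LEVELS) {
    todo <- which(is.na(lab))
    if (!length(todo)) break
    feat <- partition[partition$label == feature, , drop = FALSE]
    for (ch in unique(peaks$chrom[todo])) {
      pi <- todo[peaks$chrom[todo] == ch]
      f <- feat[feat$chrom == ch, , drop = FALSE]
      if (!nrow(f)) next
      hits <- IRanges::overlapsAny(
        IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi]),
        IRanges::IRanges(f$start + 1L, f$end))
      lab[pi[hits]] <- feature
    }
  }
  factor(lab, levels = FEATURE_LEVELS)
}

#' Feature distribution of a peak set
#'
#' Counts and fractions of peaks per feature label, paired with the
#' partition's genome-fraction baseline for enrichment reporting.
#'
#' @param peaks Interval tibble (may be empty).
#' @param partition A [build_partition()] result.
#' @return Tibble (label, peak_count, peak_fraction, genome_fraction).
#' @export
peak_feature_distribution <- function(peaks, partition) {
  lab <- classify_peaks(peaks, partition)
  cnt <- as.integer(table(lab))
  smry <- attr(partition, "summary")
  tibble::tibble(label = FEATURE_LEVELS,
                 peak_count = cnt,
                 peak_fraction = if (nrow(peaks)) cnt / nrow(peaks)
                                 else rep(0, length(FEATURE_LEVELS)),
                 genome_fraction = smry$genome_fraction)
}

#' Write a feature partition as labeled BED
#'
#' @param partition A [build_partition()] result.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  write_bed(tibble::tibble(chrom = partition$chrom, start = partition$start,
                           end = partition$end, name = partition$label,
                           score = 0, strand = "*"), path)
}
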