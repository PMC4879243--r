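# Interval-set overlap accounting: colocalization counts, Venn-style region
# arithmetic, and sharing fractions between peak collections.

#' Overlap report between two interval sets
#'
#' An A interval counts as overlapping when some B interval shares at least
#' `min_bp` bases with it; the B-side count is computed independently.
#' Shared merged regions are the connected regions of
#' `intersect(merge(A), merge(B))`.  Results do not depend on input order.
#' Intervals on chromosomes absent from the other set simply count as
#' non-overlapping.
#'
#' @param a,b Interval tibbles.
#' @param min_bp Minimum shared bases (default 1).
#' @return List of class `overlap_report`: n_a, n_b, n_a_overlap,
#'   n_b_overlap, n_shared_regions, frac_a, frac_b, min_bp.
#' @export
overlap_query <- function(a, b, min_bp = 1) {
  stopifnot(min_bp >= 1)
  count_side <- function(x, y) {
    hits <- logical(nrow(x))
    for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
      xi <- which(x$chrom == ch)
      ys <- y[y$chrom == ch, , drop = FALSE]
      hits[xi] <- IRanges::overlapsAny(
        IRanges::IRanges(x$start[xi] + 1L, x$end[xi]),
        IRanges::IRanges(ys$start + 1L, ys$end),
        minoverlap = min_bp)
    }
    sum(hits)
  }
  n_a_overlap <- count_side(a, b)
  n_b_overlap <- count_side(b, a)
  vr <- venn_regions(a, b)
  structure(list(n_a = nrow(a), n_b = nrow(b),
                 n_a_overlap = n_a_overlap, n_b_overlap = n_b_overlap,
                 n_shared_regions = nrow(vr$shared),
                 frac_a = if (nrow(a)) n_a_overlap / nrow(a) else NA_real_,
                 frac_b = if (nrow(b)) n_b_overlap / nrow(b) else NA_real_,
                 min_bp = min_bp),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0("<overlap_report> |A|=%d |B|=%d  A-with-B=%d (%.1f%%)",
                     "  B-with-A=%d (%.1f%%)  shared regions=%d",
                     "  (min_bp=%d)\n"),
              x$n_a, x$n_b, x$n_a_overlap, 100 * x$frac_a,
              x$n_b_overlap, 100 * x$frac_b, x$n_shared_regions, x$min_bp))
  invisible(x)
}

#' Venn-style region arithmetic between two interval sets
#'
#' Each set is merged internally, then split into A-only, shared and B-only
#' regions.  Base-exact: shared plus A-only bases equal merged A.
#'
#' @param a,b Interval tibbles.
#' @return List with interval tibbles `a_only`, `shared`, `b_only` and
#'   counts `n_a_only`, `n_shared`, `n_b_only`.
#' @export
venn_regions <- function(a, b) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  a_ir <- as_iranges_by_chrom(a, chroms)
  b_ir <- as_iranges_by_chrom(b, chroms)
  ops <- lapply(chroms, function(ch) {
    am <- IRanges::reduce(a_ir[[ch]]); bm <- IRanges::reduce(b_ir[[ch]])
    list(a_only = IRanges::setdiff(am, bm),
         shared = IRanges::intersect(am, bm),
         b_only = IRanges::setdiff(bm, am))
  })
  names(ops) <- chroms
  pick <- function(part)
    iranges_to_tibble(stats::setNames(lapply(ops, `[[`, part), chroms))
  a_only <- pick("a_only"); shared <- pick("shared"); b_only <- pick("b_only")
  list(a_only = a_only, shared = shared, b_only = b_only,
       n_a_only = nrow(a_only), n_shared = nrow(shared),
       n_b_only = nrow(b_only))
}

#' Fraction of A intervals overlapping B
#'
#' @param a,b Interval tibbles; `a` must be non-empty.
#' @param min_bp Minimum shared bases (default 1).
#' @return `overlap_query(a, b, min_bp)$n_a_overlap / nrow(a)`.
#' @export
fraction_of_a_in_b <- function(a, b, min_bp = 1) {
  if (!nrow(a)) stop("A is empty")
  overlap_query(a, b, min_bp)$frac_a
}
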