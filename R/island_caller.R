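# Window-based enriched-island identification with a Poisson background
# model and FDR-controlled significance against one or two control samples.
#
# The caller summarizes tags in fixed windows, pre-filters windows whose
# count clears a Poisson eligibility threshold, merges eligible windows into
# gap-tolerant islands, and tests each island's ChIP count against the
# control-derived expectation, with Benjamini-Hochberg correction per
# control at a stringent island FDR.

#' Island-caller parameters
#'
#' @param window Window size w in bp (default 200).
#' @param gap Maximum gap in bp between eligible windows merged into one
#'   island; must be a multiple of `window` (default 200).
#' @param p0 Window eligibility p-value: a window is eligible when
#'   `P(X >= count)` under the genome-wide Poisson background is below `p0`
#'   (default 0.2).
#' @param fdr Island-level FDR threshold alpha (default 1e-5).
#' @param shift Fragment shift in bp applied 3'-ward to each tag before
#'   counting (default 0).
#' @param control_mode "each": an island must pass the FDR cut against every
#'   control (intersection; default).  "pooled": controls are pooled into a
#'   single control sample first.
#' @return List of class `caller_params`.
#' @export
caller_params <- function(window = 200, gap = 200, p0 = 0.2, fdr = 1e-5,
                          shift = 0, control_mode = c("each", "pooled")) {
  control_mode <- match.arg(control_mode)
  window <- as.integer(window); gap <- as.integer(gap)
  stopifnot(window >= 1, gap >= 0, gap %% window == 0,
            p0 > 0, p0 < 1, fdr > 0, fdr < 1, shift >= 0)
  structure(list(window = window, gap = gap, p0 = p0, fdr = fdr,
                 shift = as.integer(shift), control_mode = control_mode),
            class = "caller_params")
}

#' Summarize tags in fixed windows
#'
#' Each tag is assigned to window `floor(pos' / w)` where `pos'` is the 5'
#' position moved `shift` bp 3'-ward (plus strand: +shift; minus strand:
#' -shift), clamped to the chromosome.  The total count is conserved.
#'
#' @param ts A `tag_set`.
#' @param chrom_sizes Named chromosome lengths.
#' @param window Window size in bp.
#' @param shift Fragment shift in bp.
#' @return Object of class `window_counts`: named list of per-chromosome
#'   integer count vectors, with attributes `window`, `n_tags`,
#'   `genome_length` and `lambda` (= n_tags * window / genome_length).
#' @export
count_window_tags <- function(ts, chrom_sizes, window = 200, shift = 0) {
  window <- as.integer(window)
  stopifnot(window >= 1)
  t <- ts$tags
  pos <- t$pos + ifelse(t$strand == "+", shift, -shift)
  pos <- pmax(pos, 0L)
  pos <- pmin(pos, unname(chrom_sizes[t$chrom]) - 1L)
  counts <- lapply(names(chrom_sizes), function(ch) {
    nwin <- as.integer(ceiling(chrom_sizes[[ch]] / window))
    p <- pos[t$chrom == ch]
    tabulate(p %/% window + 1L, nbins = nwin)
  })
  genome_length <- sum(as.numeric(chrom_sizes))
  structure(stats::setNames(counts, names(chrom_sizes)),
            window = window, n_tags = ts$n_tags,
            genome_length = genome_length,
            lambda = ts$n_tags * window / genome_length,
            class = "window_counts")
}

#' Poisson upper-tail probability P(X >= l)
#'
#' @param l Non-negative integer count(s).
#' @param lambda Poisson mean(s) (> 0).
#' @return `P(X >= l)`, exact, monotone non-increasing in `l`.
#' @export
poisson_upper_tail <- function(l, lambda) {
  if (any(l < 0)) stop("l must be >= 0")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  stats::ppois(l - 1, lambda, lower.tail = FALSE)
}

#' Window eligibility threshold
#'
#' Smallest integer count `l0 >= 1` whose Poisson upper tail falls below
#' `p0`.
#'
#' @param lambda Background mean per window.
#' @param p0 Eligibility p-value.
#' @return Integer threshold `l0`.
#' @export
eligible_threshold <- function(lambda, p0) {
  stopifnot(lambda > 0, p0 > 0, p0 < 1)
  l0 <- 1L
  while (poisson_upper_tail(l0, lambda) >= p0) l0 <- l0 + 1L
  l0
}

#' Merge eligible windows into candidate islands
#'
#' Maximal runs of eligible windows (count >= `l0`) in which consecutive
#' eligible windows are at most `gap` bp apart are merged into one island
#' spanning whole windows.  Ineligible gap windows contribute nothing to the
#' score; the island score is the sum over its eligible windows of
#' `-ln P(X >= count)` under the background mean.
#'
#' @param wc A `window_counts` object.
#' @param l0 Eligibility threshold from [eligible_threshold()].
#' @param gap Maximum merge gap in bp (multiple of the window size).
#' @param lambda Background mean per window (defaults to the value stored in
#'   `wc`).
#' @return Tibble of candidate islands (chrom, start, end, score,
#'   n_eligible), sorted by coordinate.
#' @export
build_islands <- function(wc, l0, gap, lambda = attr(wc, "lambda")) {
  w <- attr(wc, "window")
  stopifnot(gap %% w == 0)
  max_skip <- gap %/% w + 1L  # merge eligible windows with index diff <= this
  parts <- lapply(names(wc), function(ch) {
    cnt <- wc[[ch]]
    elig <- which(cnt >= l0)
    if (!length(elig)) return(NULL)
    grp <- cumsum(c(1L, as.integer(diff(elig) > max_skip)))
    first <- elig[!duplicated(grp)]
    last <- elig[!duplicated(grp, fromLast = TRUE)]
    sc <- -log(poisson_upper_tail(cnt[elig], lambda))
    tibble::tibble(chrom = ch,
                   start = (first - 1L) * w,
                   end = last * w,
                   score = as.numeric(tapply(sc, grp, sum)),
                   n_eligible = as.integer(tabulate(grp)))
  })
  out <- dplyr::bind_rows(parts)
  if (!nrow(out))
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), score = numeric(),
                          n_eligible = integer()))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Count tags (5'-shifted) falling in each interval of a sorted tibble.
count_tags_in <- function(ts, intervals, chrom_sizes, shift = 0) {
  t <- ts$tags
  pos <- t$pos + ifelse(t$strand == "+", shift, -shift)
  pos <- pmax(pos, 0L)
  pos <- pmin(pos, unname(chrom_sizes[t$chrom]) - 1L)
  n <- integer(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    p <- sort(pos[t$chrom == ch])
    sel <- which(intervals$chrom == ch)
    # tags in [start, end): countof pos < end minus count of pos < start
    n[sel] <- findInterval(intervals$end[sel] - 0.5, p) -
      findInterval(intervals$start[sel] - 0.5, p)
  }
  n
}

#' Island significance against a control sample
#'
#' The island's ChIP tag count is tested against a Poisson expectation
#' derived from the control: `mu = max(n_ctrl, floor) * (T_chip / T_ctrl)`,
#' with `floor` defaulting to 1 so that an empty control cannot produce a
#' zero expectation.  `p = P(Pois(mu) >= n_chip)`.  [call_islands()] raises
#' the floor to the genome-wide background expectation for the island's
#' length, which keeps a control count that randomly fluctuates low from
#' making the test anti-conservative.
#'
#' @param islands Island tibble (chrom, start, end).
#' @param chip,control `tag_set`s.
#' @param chrom_sizes Named chromosome lengths.
#' @param shift Fragment shift used in counting.
#' @param floor_counts Lower bound(s) on the control count before depth
#'   scaling (scalar or one per island; default 1).
#' @return Tibble (n_chip, n_ctrl, mu, p_value).
#' @export
island_significance <- function(islands, chip, control, chrom_sizes,
                                shift = 0, floor_counts = 1) {
  if (control$n_tags == 0) stop("control sample has no tags")
  n_chip <- count_tags_in(chip, islands, chrom_sizes, shift)
  n_ctrl <- count_tags_in(control, islands, chrom_sizes, shift)
  ratio <- chip$n_tags / control$n_tags
  mu <- pmax(n_ctrl, floor_counts, 1) * ratio
  tibble::tibble(n_chip = n_chip, n_ctrl = n_ctrl, mu = mu,
                 p_value = poisson_upper_tail(n_chip, mu))
}

# Pool several tag sets into one (concatenated tags, summed depth).
pool_tag_sets <- function(tag_sets, sample_id = "pooled") {
  tags <- dplyr::bind_rows(lapply(tag_sets, function(ts) ts$tags))
  ts1 <- tag_sets[[1]]
  tag_set(sample_id, tags$chrom, tags$pos, tags$strand,
          tag_length = ts1$tag_length)
}

#' Call significant enriched islands against control samples
#'
#' Full caller: window counting on the ChIP sample, Poisson eligibility
#' pre-filter (background mean estimated genome-wide from the ChIP sample
#' itself), gap-tolerant island aggregation, then per-control island
#' significance with Benjamini-Hochberg q-values across all candidate
#' islands.  The per-island control expectation is floored at the
#' genome-wide ChIP background expectation for the island's length (a
#' local-background floor in the tradition of sharp-peak callers), so noisy
#' low control counts cannot inflate significance.  In mode "each" an island
#' is retained iff `q <= fdr` against every control; in mode "pooled" the
#' controls are combined into one sample first.
#'
#' @param chip ChIP `tag_set` (treatment).
#' @param controls A single `tag_set` or list of them (e.g. input DNA and
#'   a knockout ChIP).
#' @param params A [caller_params()].
#' @param chrom_sizes Named chromosome lengths.
#' @return Tibble of significant islands, sorted by coordinate, with columns
#'   chrom, start, end, name, score, strand, n_chip, and per-control
#'   n_ctrl_i / p_i / q_i.  All candidate islands (with a `significant`
#'   flag) are attached as attribute `"candidates"`.
#' @export
call_islands <- function(chip, controls, params = caller_params(),
                         chrom_sizes) {
  stopifnot(inherits(params, "caller_params"))
  if (inherits(controls, "tag_set")) controls <- list(controls)
  if (!length(controls)) stop("at least one control sample is required")

  wc <- count_window_tags(chip, chrom_sizes, params$window, params$shift)
  lambda <- attr(wc, "lambda")
  l0 <- eligible_threshold(lambda, params$p0)
  cand <- build_islands(wc, l0, params$gap, lambda)
  if (!nrow(cand)) {
    out <- empty_island_tibble(length(controls))
    attr(out, "candidates") <- out
    return(out)
  }

  if (params$control_mode == "pooled" && length(controls) > 1)
    controls <- list(pool_tag_sets(controls))

  # genome-wide background expectation for each island's length, in
  # chip-count units (the floor applied before depth scaling).
  bg_floor <- chip$n_tags * (cand$end - cand$start) /
    attr(wc, "genome_length")

  keep <- rep(TRUE, nrow(cand))
  first <- TRUE
  for (i in seq_along(controls)) {
    sig <- island_significance(cand, chip, controls[[i]], chrom_sizes,
                               shift = params$shift,
                               floor_counts = bg_floor /
                                 (chip$n_tags / controls[[i]]$n_tags))
    if (first) { cand$n_chip <- sig$n_chip; first <- FALSE }
    q <- stats::p.adjust(sig$p_value, method = "BH")
    cand[[paste0("n_ctrl_", i)]] <- sig$n_ctrl
    cand[[paste0("p_", i)]] <- sig$p_value
    cand[[paste0("q_", i)]] <- q
    keep <- keep & (q <= params$fdr)
  }
  cand$significant <- keep
  cand$name <- sprintf("island_%05d", seq_len(nrow(cand)))
  cand$strand <- "*"
  out <- cand[keep, , drop = FALSE]
  attr(out, "candidates") <- cand
  out
}

empty_island_tibble <- function(n_controls) {
  out <- tibble::tibble(chrom = character(), start = integer(),
                        end = integer(), score = numeric(),
                        n_eligible = integer(), n_chip = integer())
  for (i in seq_len(n_controls)) {
    out[[paste0("n_ctrl_", i)]] <- integer()
    out[[paste0("p_", i)]] <- numeric()
    out[[paste0("q_", i)]] <- numeric()
  }
  out$significant <- logical()
  out$name <- character()
  out$strand <- character()
  out
}

#' Compare called islands with a planted truth set
#'
#' A planted interval counts as recovered when some called island overlaps
#' it with reciprocal overlap at least `min_reciprocal` (the shared bases
#' are at least that fraction of both interval lengths); a called island is
#' a true positive under the same criterion.
#'
#' @param called Island tibble (chrom, start, end).
#' @param truth Planted interval tibble.
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return List: n_called, n_truth, recall, precision.
#' @export
island_recovery_stats <- function(called, truth, min_reciprocal = 0.5) {
  if (!nrow(truth))
    return(list(n_called = nrow(called), n_truth = 0L,
                recall = NA_real_, precision = NA_real_))
  hit_truth <- rep(FALSE, nrow(truth))
  hit_called <- rep(FALSE, nrow(called))
  for (ch in unique(truth$chrom)) {
    ti <- which(truth$chrom == ch)
    ci <- which(called$chrom == ch)
    if (!length(ci)) next
    for (i in ti) {
      ov <- pmin(truth$end[i], called$end[ci]) -
        pmax(truth$start[i], called$start[ci])
      rec <- ov >= min_reciprocal * (truth$end[i] - truth$start[i]) &
        ov >= min_reciprocal * (called$end[ci] - called$start[ci])
      if (any(rec)) {
        hit_truth[i] <- TRUE
        hit_called[ci[rec]] <- TRUE
      }
    }
  }
  list(n_called = nrow(called), n_truth = nrow(truth),
       recall = mean(hit_truth),
       precision = if (nrow(called)) mean(hit_called) else NA_real_)
}

#' Write window counts as bedGraph
#'
#' @param wc A `window_counts` object.
#' @param chrom_sizes Named chromosome lengths.
#' @param path Output path.
#' @param omit_zero Skip zero-count windows (default TRUE).
#' @export
write_bedgraph <- function(wc, chrom_sizes, path, omit_zero = TRUE) {
  w <- attr(wc, "window")
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(wc)) {
    cnt <- wc[[ch]]
    idx <- if (omit_zero) which(cnt > 0) else seq_along(cnt)
    if (!length(idx)) next
    utils::write.table(
      data.frame(ch, (idx - 1L) * w,
                 pmin(idx * w, chrom_sizes[[ch]]), cnt[idx]),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
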