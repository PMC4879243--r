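# Average tag-density metaprofiles around reference points and along
# percentile-scaled gene bodies.
#
# Normalization follows the pooled-base convention: each bin's density is
# its total tag count divided by the total number of in-bounds bases it
# covers (summed over all profiled regions) and by the library size, scaled
# by 1e6 for readability (tags per base per million tags).

PROFILE_SCALE <- 1e6

#' Metaprofile specification
#'
#' @param mode "reference_point" (fixed flanks around a point, e.g. TSS or
#'   CpG-island centre) or "scaled_gene_body" (fixed-width flanks plus
#'   percentile body bins).
#' @param flank Flank extent in bp on each side (default 5000 for reference
#'   points; use 3000 for gene-body profiles).
#' @param bin Flank bin width in bp (default 100); `flank` must be a
#'   multiple of `bin`.
#' @param n_body_bins Number of percentile bins along the gene body
#'   (default 20, i.e. 5% each); only used in scaled_gene_body mode.
#' @param strand_aware Flip bin order for "-" strand regions so bins always
#'   run 5' to 3' (default TRUE).
#' @return List of class `profile_spec`.
#' @export
profile_spec <- function(mode = c("reference_point", "scaled_gene_body"),
                         flank = 5000, bin = 100, n_body_bins = 20,
                         strand_aware = TRUE) {
  mode <- match.arg(mode)
  flank <- as.integer(flank); bin <- as.integer(bin)
  n_body_bins <- as.integer(n_body_bins)
  stopifnot(flank >= 0, bin >= 1, flank %% bin == 0, n_body_bins >= 1)
  structure(list(mode = mode, flank = flank, bin = bin,
                 n_body_bins = n_body_bins, strand_aware = strand_aware),
            class = "profile_spec")
}

profile_tibble <- function(labels, bases, counts, n_tags, spec,
                           n_skipped = 0L) {
  density <- ifelse(bases > 0, counts / (bases * max(n_tags, 1)) *
                      PROFILE_SCALE, 0)
  structure(tibble::tibble(bin_label = labels,
                           bin_index = seq_along(labels) - 1L,
                           bases = bases, count = counts, density = density),
            spec = spec, n_tags = n_tags, scale = PROFILE_SCALE,
            n_skipped = n_skipped,
            class = c("metaprofile", "tbl_df", "tbl", "data.frame"))
}

#' Tag-density profile around reference points
#'
#' Bins of width `spec$bin` cover `[point - flank, point + flank)` around
#' each point; a tag overlapping several points' windows is counted once per
#' window.  For "-" strand points (when `strand_aware`) the bin order is
#' flipped so bins run 5' to 3'.  Bins truncated at chromosome edges
#' contribute only their in-bounds bases to the denominator.
#'
#' @param ts A `tag_set`.
#' @param points Tibble (chrom, pos, strand) of reference points; strand
#'   "*" is treated as "+".
#' @param spec A [profile_spec()] with mode "reference_point".
#' @param chrom_sizes Named chromosome lengths.
#' @return A `metaprofile` tibble (bin_label, bases, count, density).
#' @export
reference_point_profile <- function(ts, points, spec, chrom_sizes) {
  stopifnot(inherits(spec, "profile_spec"), spec$mode == "reference_point")
  if (!nrow(points)) stop("no reference points supplied")
  nb <- 2L * spec$flank %/% spec$bin
  counts <- numeric(nb); bases <- numeric(nb)
  flip <- spec$strand_aware & points$strand == "-"

  for (ch in unique(points$chrom)) {
    L <- chrom_sizes[[ch]]
    if (is.null(L)) stop("unknown chromosome: ", ch)
    sel <- which(points$chrom == ch)
    p <- points$pos[sel]
    tagpos <- sort(ts$tags$pos[ts$tags$chrom == ch])
    win_start <- p - spec$flank
    # tags per point window, vectorized over points via sorted positions
    lo <- findInterval(win_start - 0.5, tagpos)
    hi <- findInterval(p + spec$flank - 0.5, tagpos)
    for (k in seq_along(sel)) {
      if (hi[k] > lo[k]) {
        tp <- tagpos[(lo[k] + 1):hi[k]]
        b <- (tp - win_start[k]) %/% spec$bin
        if (flip[sel[k]]) b <- nb - 1L - b
        tb <- tabulate(b + 1L, nbins = nb)
        counts <- counts + tb
      }
      # in-bounds bases per bin for this point
      bs <- win_start[k] + spec$bin * (0:(nb - 1L))
      be <- bs + spec$bin
      wdt <- pmax(0, pmin(be, L) - pmax(bs, 0))
      if (flip[sel[k]]) wdt <- rev(wdt)
      bases <- bases + wdt
    }
  }
  labels <- sprintf("[%d,%d)", -spec$flank + spec$bin * (0:(nb - 1L)),
                    -spec$flank + spec$bin * (1:nb))
  profile_tibble(labels, bases, counts, ts$n_tags, spec)
}

#' Tag-density profile along scaled gene bodies
#'
#' Per gene: `flank/bin` upstream bins of width `bin`, `n_body_bins`
#' percentile bins each covering `floor` fractions of that gene's length
#' (the remainder bases go to the last body bin), and `flank/bin`
#' downstream bins.  "-" strand genes are traversed 3' to 5' and flipped so
#' bin order is always upstream -> TSS -> TTS -> downstream.  Genes shorter
#' than `n_body_bins` bp are skipped; their number is recorded in the
#' `n_skipped` attribute.
#'
#' @param ts A `tag_set`.
#' @param genes Gene tibble.
#' @param spec A [profile_spec()] with mode "scaled_gene_body" (use
#'   `flank = 3000` for the conventional 3-kb flanks).
#' @param chrom_sizes Named chromosome lengths.
#' @return A `metaprofile` tibble with `2*flank/bin + n_body_bins` rows.
#' @export
gene_body_profile <- function(ts, genes, spec, chrom_sizes) {
  stopifnot(inherits(spec, "profile_spec"), spec$mode == "scaled_gene_body")
  if (!nrow(genes)) stop("no genes supplied")
  n_up <- spec$flank %/% spec$bin
  nb <- spec$n_body_bins
  ntot <- 2L * n_up + nb
  counts <- numeric(ntot); bases <- numeric(ntot)
  n_skipped <- 0L

  tag_by_chrom <- split(ts$tags$pos, ts$tags$chrom)
  tag_by_chrom <- lapply(tag_by_chrom, sort)

  for (i in seq_len(nrow(genes))) {
    L <- genes$end[i] - genes$start[i]
    if (L < nb) { n_skipped <- n_skipped + 1L; next }
    chromL <- chrom_sizes[[genes$chrom[i]]]
    if (is.null(chromL)) stop("unknown chromosome: ", genes$chrom[i])
    minus <- spec$strand_aware && genes$strand[i] == "-"
    # breaks in transcript-relative coordinates (0 = TSS, L = TTS+1 side)
    rel_breaks <- c(-spec$flank + spec$bin * (0:(n_up - 1L)),
                    floor((0:(nb - 1L)) * L / nb),
                    L + spec$bin * (0:n_up))
    # absolute half-open bin [a_j, b_j)
    if (!minus) {
      abs_lo <- genes$start[i] + rel_breaks[-length(rel_breaks)]
      abs_hi <- genes$start[i] + rel_breaks[-1]
    } else {
      abs_lo <- genes$end[i] - rel_breaks[-1]
      abs_hi <- genes$end[i] - rel_breaks[-length(rel_breaks)]
    }
    tagpos <- tag_by_chrom[[genes$chrom[i]]]
    if (!is.null(tagpos) && length(tagpos)) {
      lo_all <- min(abs_lo); hi_all <- max(abs_hi)
      a <- findInterval(lo_all - 0.5, tagpos)
      b <- findInterval(hi_all - 0.5, tagpos)
      if (b > a) {
        tp <- tagpos[(a + 1):b]
        if (!minus) {
          rel <- tp - genes$start[i]
        } else {
          rel <- genes$end[i] - 1L - tp
        }
        brk <- rel_breaks
        j <- findInterval(rel, brk)  # 1..ntot for rel in [brk[1], brk[end])
        ok <- j >= 1 & j <= ntot & rel >= brk[1]
        counts <- counts + tabulate(j[ok], nbins = ntot)
      }
    }
    # abs_lo/abs_hi are indexed in transcript (rel) bin order for both
    # strands, so the clipped widths line up with the bins directly.
    wdt <- pmax(0, pmin(abs_hi, chromL) - pmax(abs_lo, 0))
    bases <- bases + wdt
  }
  labels <- c(sprintf("up%d", -spec$flank + spec$bin * (0:(n_up - 1L))),
              sprintf("body%02d", seq_len(nb)),
              sprintf("down+%d", spec$bin * (0:(n_up - 1L))))
  profile_tibble(labels, bases, counts, ts$n_tags, spec,
                 n_skipped = n_skipped)
}

#' Align several profiles into a long table
#'
#' @param profiles Named list of `metaprofile`s computed with identical
#'   specs.
#' @return Long tibble (sample, bin_index, bin_label, density).
#' @export
profiles_compare <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  specs <- lapply(profiles, attr, "spec")
  ref <- specs[[1]]
  same <- vapply(specs, identical, TRUE, y = ref)
  if (!all(same)) stop("profiles have mismatched specs")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("sample", seq_along(profiles))
  dplyr::bind_rows(lapply(names(profiles), function(nm)
    tibble::tibble(sample = nm,
                   bin_index = profiles[[nm]]$bin_index,
                   bin_label = profiles[[nm]]$bin_label,
                   density = profiles[[nm]]$density)))
}

#' Write a metaprofile as TSV with a header
#'
#' Header lines (prefixed `#`) record the spec, library size and scale.
#'
#' @param profile A `metaprofile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  spec <- attr(profile, "spec")
  hdr <- c(sprintf("# mode: %s", spec$mode),
           sprintf("# flank: %d", spec$flank),
           sprintf("# bin: %d", spec$bin),
           sprintf("# n_body_bins: %d", spec$n_body_bins),
           sprintf("# n_tags: %d", attr(profile, "n_tags")),
           sprintf("# scale: %g", attr(profile, "scale")),
           sprintf("# n_skipped: %d", attr(profile, "n_skipped")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
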