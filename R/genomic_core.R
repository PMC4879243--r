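# Core coordinate conventions and file plumbing.
#
# All coordinates are 0-based half-open ([start, end)), the BED convention.
# Intervals travel as plain tibbles with columns chrom, start, end and
# optionally name, strand ("+", "-", "*").  1-based containers (IRanges) are
# only built transiently inside set-arithmetic helpers.

#' Read a two-column chromosome-sizes table
#'
#' @param path Path to a tab-separated file with columns chrom name and
#'   length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chrom_sizes(stats::setNames(df$length, df$chrom))
}

#' Construct a validated chromosome-sizes vector
#'
#' @param sizes Named numeric vector, names unique, lengths >= 1.
#' @return Named integer vector.
#' @export
chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || anyNA(names(sizes)) || any(names(sizes) == ""))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(sizes)))
    stop("duplicated chromosome names")
  if (any(sizes < 1))
    stop("chromosome lengths must be >= 1")
  stats::setNames(as.integer(sizes), names(sizes))
}

#' Write a chromosome-sizes table
#'
#' @param sizes Named vector of lengths.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), unname(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a validated interval tibble
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand "+", "-" or "*" (unstranded); recycled.
#' @param name Optional name column.
#' @param chrom_sizes Optional named lengths; when given, intervals must lie
#'   within their chromosome.
#' @return Tibble with columns chrom, start, end, name, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NULL,
                              chrom_sizes = NULL) {
  x <- tibble::tibble(chrom = as.character(chrom),
                      start = as.integer(start), end = as.integer(end),
                      name = if (is.null(name)) "." else as.character(name),
                      strand = as.character(strand))
  validate_intervals(x, chrom_sizes)
}

#' Validate an interval tibble
#'
#' Checks 0 <= start < end, strand values, and (optionally) chromosome bounds.
#'
#' @param x Interval tibble.
#' @param chrom_sizes Optional named lengths.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1],
         ": ", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]])
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    if (any(x$end > chrom_sizes[x$chrom]))
      stop("interval extends past chromosome end")
  }
  x
}

#' Read a BED3/BED6 file as an interval tibble
#'
#' Coordinates are taken as 0-based half-open.  Strand comes from column 6
#' when present, otherwise "*".  Input order is preserved.
#'
#' @param path Path to a tab-separated BED file.
#' @return Interval tibble (chrom, start, end, name, score, strand).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 fields")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1], " in ",
         path, ": non-integer coordinate")
  x <- tibble::tibble(chrom = get(1, NA),
                      start = start, end = end,
                      name = get(4, "."),
                      score = suppressWarnings(as.numeric(get(5, "0"))),
                      strand = get(6, "*"))
  x$score[is.na(x$score)] <- 0
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval at BED line ", bad[1], " in ", path,
         ": start >= end")
  validate_intervals(x)
}

#' Write an interval tibble as BED
#'
#' Writes BED6 when strand or name information is present, else BED3.
#' Round-trips with [read_bed()].
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  bed6 <- any(strand != "*") || any(name != ".") || any(score != 0)
  df <- if (bed6)
    data.frame(x$chrom, x$start, x$end, name, score, strand)
  else
    data.frame(x$chrom, x$start, x$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

#' Read a refFlat-like gene table
#'
#' Expected tab-separated columns: gene_id, chrom, strand, txStart, txEnd,
#' exonCount, exonStarts, exonEnds.  Exon start/end lists are comma-separated
#' (a trailing comma is accepted).  Coordinates are 0-based half-open.
#' Exon blocks must be sorted, disjoint, contained in the gene span, with the
#' first block starting at txStart and the last ending at txEnd.
#'
#' @param path Path to the gene table.
#' @return Gene tibble: gene_id, chrom, strand, start, end and list-columns
#'   exon_starts, exon_ends.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "chrom", "strand",
                                        "txStart", "txEnd", "exonCount",
                                        "exonStarts", "exonEnds"),
                          colClasses = "character")
  parse_list <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  genes <- tibble::tibble(
    gene_id = df$gene_id, chrom = df$chrom, strand = df$strand,
    start = as.integer(df$txStart), end = as.integer(df$txEnd),
    exon_starts = lapply(df$exonStarts, parse_list),
    exon_ends = lapply(df$exonEnds, parse_list))
  validate_genes(genes)
}

#' Validate a gene tibble
#'
#' @param genes Gene tibble as returned by [read_gene_table()].
#' @return `genes`, or an error describing the violated exon-block invariant.
#' @export
validate_genes <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end",
                  "exon_starts", "exon_ends") %in% names(genes)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$start >= genes$end))
    stop("gene span must satisfy start < end")
  for (i in seq_len(nrow(genes))) {
    s <- genes$exon_starts[[i]]; e <- genes$exon_ends[[i]]
    id <- genes$gene_id[i]
    if (length(s) != length(e))
      stop("gene ", id, ": exonStarts and exonEnds lengths differ")
    if (!length(s)) stop("gene ", id, ": no exons")
    if (any(s >= e)) stop("gene ", id, ": empty exon block")
    if (is.unsorted(s, strictly = TRUE) ||
        any(s[-1] < e[-length(e)]))
      stop("gene ", id, ": exons not sorted/disjoint")
    if (s[1] != genes$start[i] || e[length(e)] != genes$end[i] ||
        any(s < genes$start[i]) || any(e > genes$end[i]))
      stop("gene ", id, ": exon blocks must span [txStart, txEnd)")
  }
  genes
}

#' Write a gene tibble as a refFlat-like table
#'
#' @param genes Gene tibble.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  fmt <- function(l) vapply(l, function(v) paste0(paste(v, collapse = ","), ","), "")
  df <- data.frame(genes$gene_id, genes$chrom, genes$strand,
                   genes$start, genes$end, lengths(genes$exon_starts),
                   fmt(genes$exon_starts), fmt(genes$exon_ends))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transcription start / termination sites
#'
#' TSS of a "+" gene is `start`; of a "-" gene, `end - 1` (the last base of
#' the span).  TTS is the symmetric opposite.  "Upstream" is always
#' strand-relative.
#'
#' @param genes Gene tibble.
#' @return Integer vector of 0-based positions.
#' @export
tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' @rdname tss
#' @export
tts <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

#' Clip intervals to chromosome bounds
#'
#' Starts are clamped to >= 0 and ends to the chromosome length.  Intervals
#' that become empty are dropped; their number is recorded in the
#' `"n_empty"` attribute.
#'
#' @param x Interval tibble.
#' @param chrom_sizes Named chromosome lengths.
#' @return Clipped interval tibble with attribute `n_empty`.
#' @export
clip_intervals <- function(x, chrom_sizes) {
  unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  x$start <- pmax(x$start, 0L)
  x$end <- pmin(x$end, unname(chrom_sizes[x$chrom]))
  empty <- x$start >= x$end
  out <- x[!empty, , drop = FALSE]
  attr(out, "n_empty") <- sum(empty)
  out
}

# ---- tag sets --------------------------------------------------------------

#' Construct a tag set
#'
#' A tag is the 5' genomic position of a uniquely mapped read.  `n_tags`
#' (the library size T) is always the number of stored tags.
#'
#' @param sample_id Sample name.
#' @param chrom,pos,strand Parallel vectors: chromosome, 0-based 5' position,
#'   strand ("+"/"-").
#' @param tag_length Read length in bp (metadata only; default 50).
#' @param chrom_sizes Optional named lengths for bounds checking.
#' @return Object of class `tag_set`.
#' @export
tag_set <- function(sample_id, chrom, pos, strand, tag_length = 50L,
                    chrom_sizes = NULL) {
  tags <- tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                         strand = as.character(strand))
  if (!all(tags$strand %in% c("+", "-")))
    stop("tag strand must be '+' or '-'")
  if (any(tags$pos < 0)) stop("tag positions must be >= 0")
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(tags$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("tags on unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(tags$pos >= chrom_sizes[tags$chrom]))
      stop("tag position past chromosome end")
  }
  structure(list(sample_id = sample_id, tags = tags,
                 n_tags = nrow(tags), tag_length = as.integer(tag_length)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("<tag_set> ", x$sample_id, ": ", x$n_tags, " tags (",
      x$tag_length, " bp) on ", length(unique(x$tags$chrom)),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read tags from a BED6 file
#'
#' Each BED interval represents one read; its 5' position is `start` on the
#' "+" strand and `end - 1` on the "-" strand.
#'
#' @param path BED6 path.
#' @param sample_id Sample name (default: file base name).
#' @param tag_length Read length metadata.
#' @param dedup Drop duplicate (chrom, pos, strand) tags when TRUE.
#'   Default FALSE: duplicates are kept.
#' @param chrom_sizes Optional bounds check.
#' @return A `tag_set`.
#' @export
read_tags <- function(path, sample_id = NULL, tag_length = 50L,
                      dedup = FALSE, chrom_sizes = NULL) {
  bed <- read_bed(path)
  if (nrow(bed) && !all(bed$strand %in% c("+", "-")))
    stop("tag BED requires stranded entries")
  pos <- ifelse(bed$strand == "+", bed$start, bed$end - 1L)
  if (dedup) {
    keep <- !duplicated(paste(bed$chrom, pos, bed$strand))
    bed <- bed[keep, , drop = FALSE]; pos <- pos[keep]
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.bed$", "", basename(path))
  tag_set(sample_id, bed$chrom, pos, bed$strand, tag_length = tag_length,
          chrom_sizes = chrom_sizes)
}

#' Write a tag set as BED6
#'
#' Inverse of [read_tags()]: a "+" tag at `pos` becomes
#' `[pos, pos + tag_length)`, a "-" tag `[pos - tag_length + 1, pos + 1)`
#' (clamped at the origin).
#'
#' @param ts A `tag_set`.
#' @param path Output path.
#' @export
write_tags <- function(ts, path) {
  t <- ts$tags
  start <- ifelse(t$strand == "+", t$pos, pmax(t$pos - ts$tag_length + 1L, 0L))
  end <- ifelse(t$strand == "+", t$pos + ts$tag_length, t$pos + 1L)
  write_bed(tibble::tibble(chrom = t$chrom, start = start, end = end,
                           name = ts$sample_id, score = 0, strand = t$strand),
            path)
}

# ---- internal interval helpers (IRanges-backed) ----------------------------

# Split an interval tibble into a per-chromosome list of IRanges (1-based).
as_iranges_by_chrom <- function(x, chroms = NULL) {
  if (is.null(chroms)) chroms <- unique(x$chrom)
  out <- lapply(chroms, function(ch) {
    sel <- x$chrom == ch
    IRanges::IRanges(start = x$start[sel] + 1L, end = x$end[sel])
  })
  stats::setNames(out, chroms)
}

# Back-convert a named list of IRanges into an interval tibble.
iranges_to_tibble <- function(irl) {
  parts <- lapply(names(irl), function(ch) {
    ir <- irl[[ch]]
    tibble::tibble(chrom = rep(ch, length(ir)),
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir))
  })
  out <- dplyr::bind_rows(parts)
  if (!nrow(out))
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())
  out
}
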