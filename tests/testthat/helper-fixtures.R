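# Shared fixtures and independent oracles, all built in code.

toy_sizes <- function() chrom_sizes(c(chrA = 10000))

# One "+" gene [4000,6000) with exons [4000,4500) and [5500,6000).
toy_genes <- function(strand = "+") {
  validate_genes(tibble::tibble(
    gene_id = "g1", chrom = "chrA", strand = strand,
    start = 4000L, end = 6000L,
    exon_starts = list(c(4000L, 5500L)),
    exon_ends = list(c(4500L, 6000L))))
}

make_tags <- function(chrom, pos, strand = "+", id = "t",
                      chrom_sizes = NULL) {
  n <- length(pos)
  tag_set(id, rep_len(chrom, n), pos, rep_len(strand, n),
          chrom_sizes = chrom_sizes)
}

random_intervals <- function(n, chroms, max_pos, max_len = 200,
                             min_len = 1) {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(max_pos - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len - min_len + 1L, n, replace = TRUE) +
    min_len - 1L
  tibble::tibble(chrom = ch, start = st, end = st + len)
}

# All-pairs brute-force overlap counts (chunked so 1e4 x 1e4 stays cheap).
brute_overlap_counts <- function(a, b, min_bp = 1) {
  count_one_way <- function(x, y) {
    hit <- logical(nrow(x))
    for (ch in unique(x$chrom)) {
      xi <- which(x$chrom == ch)
      yi <- which(y$chrom == ch)
      if (!length(yi)) next
      for (chunk in split(xi, ceiling(seq_along(xi) / 500))) {
        ov <- outer(x$end[chunk], y$end[yi], pmin) -
          outer(x$start[chunk], y$start[yi], pmax)
        hit[chunk] <- hit[chunk] | (apply(ov, 1, max) >= min_bp)
      }
    }
    sum(hit)
  }
  list(n_a_overlap = count_one_way(a, b), n_b_overlap = count_one_way(b, a))
}

# Per-base coverage oracle for venn-style region counts (small genomes).
coverage_venn_oracle <- function(a, b, chrom_lengths) {
  res <- c(a_only = 0L, shared = 0L, b_only = 0L,
           bp_a_only = 0, bp_shared = 0, bp_b_only = 0)
  for (ch in names(chrom_lengths)) {
    cov_of <- function(x) {
      v <- logical(chrom_lengths[[ch]])
      xi <- which(x$chrom == ch)
      for (i in xi) v[(x$start[i] + 1):x$end[i]] <- TRUE
      v
    }
    va <- cov_of(a); vb <- cov_of(b)
    count_runs <- function(v) {
      r <- rle(v)
      sum(r$values)
    }
    res["a_only"] <- res["a_only"] + count_runs(va & !vb)
    res["shared"] <- res["shared"] + count_runs(va & vb)
    res["b_only"] <- res["b_only"] + count_runs(!va & vb)
    res["bp_a_only"] <- res["bp_a_only"] + sum(va & !vb)
    res["bp_shared"] <- res["bp_shared"] + sum(va & vb)
    res["bp_b_only"] <- res["bp_b_only"] + sum(!va & vb)
  }
  res
}

# Per-base feature labeling oracle with promoter > exon > intron precedence.
per_base_labels <- function(genes, chrom_sizes, promoter_len) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    lab <- rep("intergenic", chrom_sizes[[ch]])
    gi <- which(genes$chrom == ch)
    for (i in gi)  # introns first, lowest precedence of the gene labels
      lab[(genes$start[i] + 1):genes$end[i]] <- "intron"
    for (i in gi) {
      s <- genes$exon_starts[[i]]; e <- genes$exon_ends[[i]]
      for (j in seq_along(s)) lab[(s[j] + 1):e[j]] <- "exon"
    }
    for (i in gi) {
      t0 <- tss(genes[i, ])
      p <- if (genes$strand[i] == "+") c(t0 - promoter_len, t0)
           else c(t0 + 1L, t0 + 1L + promoter_len)
      p <- pmax(pmin(p, chrom_sizes[[ch]]), 0L)
      if (p[1] < p[2]) lab[(p[1] + 1):p[2]] <- "promoter"
    }
    out[[ch]] <- lab
  }
  out
}

# Minimal genome wrapper for tag simulation on a bare chromosome set.
bare_genome <- function(sizes) {
  list(chrom_sizes = sizes,
       genes = tibble::tibble(),
       cpgi = tibble::tibble(),
       truth = list(enriched = tibble::tibble(chrom = character(),
                                              start = integer(),
                                              end = integer(),
                                              fold = numeric())))
}
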