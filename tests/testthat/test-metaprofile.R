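test_that("reference-point binning places tags and truncates at edges", {
  cs <- chrom_sizes(c(chrA = 10000))
  spec <- profile_spec("reference_point", flank = 500, bin = 100)
  pts <- tibble::tibble(chrom = "chrA", pos = 5000L, strand = "+")

  p0 <- reference_point_profile(make_tags("chrA", integer(0)), pts, spec, cs)
  expect_equal(nrow(p0), 10)
  expect_true(all(p0$density == 0))

  p1 <- reference_point_profile(make_tags("chrA", 4950L), pts, spec, cs)
  expect_equal(p1$bin_label[p1$count > 0], "[-100,0)")
  expect_equal(sum(p1$count), 1)

  # minus-strand point flips the bin order
  ptsm <- tibble::tibble(chrom = "chrA", pos = 5000L, strand = "-")
  p2 <- reference_point_profile(make_tags("chrA", 4950L), ptsm, spec, cs)
  expect_equal(p2$bin_label[p2$count > 0], "[0,100)")

  # point near the origin: out-of-bounds bases leave the denominator
  pts0 <- tibble::tibble(chrom = "chrA", pos = 200L, strand = "+")
  p3 <- reference_point_profile(make_tags("chrA", 100L), pts0, spec, cs)
  expect_equal(p3$bases, c(0, 0, 0, 100, 100, 100, 100, 100, 100, 100))
  expect_error(reference_point_profile(make_tags("chrA", 1L), pts0[0, ],
                                       spec, cs),
               "points")
})

test_that("deterministic uniform tags give an exactly flat profile", {
  cs <- chrom_sizes(c(chrA = 20000))
  ts <- make_tags("chrA", 0:19999)
  spec <- profile_spec("reference_point", flank = 1000, bin = 100)
  pts <- tibble::tibble(chrom = "chrA", pos = c(5000L, 9000L, 15000L),
                        strand = c("+", "-", "+"))
  p <- reference_point_profile(ts, pts, spec, cs)
  expect_true(all(p$density == p$density[1]))
  expect_equal(p$density[1], 1 / (20000) * 1e6)  # C/(B*T)*scale = 100/(300*2e4)*1e6
})

test_that("gene-body profiles scale bodies into percentile bins", {
  cs <- chrom_sizes(c(chrA = 10000))
  genes <- validate_genes(tibble::tibble(
    gene_id = "g1", chrom = "chrA", strand = "+", start = 4000L,
    end = 6000L, exon_starts = list(4000L), exon_ends = list(6000L)))
  spec <- profile_spec("scaled_gene_body", flank = 3000, bin = 100)

  p0 <- gene_body_profile(make_tags("chrA", integer(0)), genes, spec, cs)
  expect_equal(nrow(p0), 80)  # 30 + 20 + 30
  expect_true(all(p0$count == 0))

  # body bins of a 2000-bp gene are 100 bp; tag at TSS+150 -> body bin 2
  p1 <- gene_body_profile(make_tags("chrA", 4150L), genes, spec, cs)
  expect_equal(p1$bin_label[p1$count > 0], "body02")
  # upstream tag 250 bp before TSS -> third upstream bin from TSS
  p2 <- gene_body_profile(make_tags("chrA", 3750L), genes, spec, cs)
  expect_equal(p2$bin_label[p2$count > 0], "up-300")

  # minus-strand gene: tag 150 bp downstream of its TSS (at end-1)
  genes_m <- genes; genes_m$strand <- "-"
  p3 <- gene_body_profile(make_tags("chrA", 5849L), genes_m, spec, cs)
  expect_equal(p3$bin_label[p3$count > 0], "body02")

  # genes shorter than the bin count are skipped with a tally
  tiny <- validate_genes(tibble::tibble(
    gene_id = "t", chrom = "chrA", strand = "+", start = 100L, end = 110L,
    exon_starts = list(100L), exon_ends = list(110L)))
  p4 <- gene_body_profile(make_tags("chrA", 105L),
                          dplyr::bind_rows(genes, tiny), spec, cs)
  expect_equal(attr(p4, "n_skipped"), 1L)
})

test_that("profile counts are conserved and depth-invariant", {
  set.seed(12)
  cs <- chrom_sizes(c(chrA = 5e4, chrB = 5e4))
  pos <- sample.int(5e4, 4000, TRUE) - 1L
  ch <- sample(c("chrA", "chrB"), 4000, TRUE)
  ts <- make_tags(ch, pos, sample(c("+", "-"), 4000, TRUE))
  pts <- tibble::tibble(chrom = c("chrA", "chrA", "chrB"),
                        pos = c(10000L, 10500L, 30000L),
                        strand = c("+", "-", "+"))
  spec <- profile_spec("reference_point", flank = 2000, bin = 100)
  p <- reference_point_profile(ts, pts, spec, cs)
  # conservation: one count per tag per covering window (overlap counted twice)
  expected <- sum(vapply(seq_len(nrow(pts)), function(i) {
    sum(ts$tags$chrom == pts$chrom[i] &
          ts$tags$pos >= pts$pos[i] - 2000 &
          ts$tags$pos < pts$pos[i] + 2000)
  }, 0))
  expect_equal(sum(p$count), expected)

  # doubling depth by duplicating every tag leaves density unchanged
  ts2 <- make_tags(c(ch, ch), c(pos, pos),
                   c(ts$tags$strand, ts$tags$strand))
  p2 <- reference_point_profile(ts2, pts, spec, cs)
  expect_equal(p2$density, p$density)
})

test_that("strand-aware profiles are mirror-symmetric", {
  set.seed(13)
  L <- 30000L
  cs <- chrom_sizes(c(chrA = L))
  pos <- sample.int(L, 2000, TRUE) - 1L
  str <- sample(c("+", "-"), 2000, TRUE)
  ts <- make_tags("chrA", pos, str)
  # mirrored genome: position p -> L-1-p, strands flipped
  flip <- c("+" = "-", "-" = "+")
  ts_m <- make_tags("chrA", L - 1L - pos, unname(flip[str]))
  genes <- validate_genes(tibble::tibble(
    gene_id = c("a", "b"), chrom = "chrA", strand = c("+", "-"),
    start = c(8000L, 20000L), end = c(10000L, 24000L),
    exon_starts = list(8000L, 20000L), exon_ends = list(10000L, 24000L)))
  genes_m <- validate_genes(tibble::tibble(
    gene_id = c("a", "b"), chrom = "chrA",
    strand = unname(flip[genes$strand]),
    start = L - genes$end, end = L - genes$start,
    exon_starts = lapply(seq_len(2), function(i) L - genes$exon_ends[[i]]),
    exon_ends = lapply(seq_len(2), function(i) L - genes$exon_starts[[i]])))
  spec <- profile_spec("scaled_gene_body", flank = 2000, bin = 100)
  p <- gene_body_profile(ts, genes, spec, cs)
  pm <- gene_body_profile(ts_m, genes_m, spec, cs)
  expect_equal(pm$count, p$count)
  expect_equal(pm$density, p$density)
})

test_that("profiles_compare aligns samples and rejects mixed specs", {
  cs <- chrom_sizes(c(chrA = 10000))
  spec <- profile_spec("reference_point", flank = 500, bin = 100)
  pts <- tibble::tibble(chrom = "chrA", pos = 5000L, strand = "+")
  ts <- make_tags("chrA", c(4600L, 4950L, 5100L))
  pa <- reference_point_profile(ts, pts, spec, cs)
  pb <- reference_point_profile(ts, pts, spec, cs)
  cmp <- profiles_compare(list(wt = pa, ko = pb))
  expect_equal(nrow(cmp), 20)
  expect_equal(cmp$density[cmp$sample == "wt"],
               cmp$density[cmp$sample == "ko"])
  pc <- reference_point_profile(
    ts, pts, profile_spec("reference_point", flank = 600, bin = 100), cs)
  expect_error(profiles_compare(list(pa, pc)), "mismatched")
  expect_error(profiles_compare(list()), "no profiles")
})
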