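test_that("generators are fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_genes = 50, chrom_length = 5e5,
                    n_cpgi = 20, depth = 2e4, n_direct_targets = 10,
                    n_bound_unchanged = 2)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  t1 <- simulate_chip_tags(g1, cfg, "treatment", "chip")
  t2 <- simulate_chip_tags(g2, cfg, "treatment", "chip")
  expect_identical(t1, t2)
  e1 <- simulate_expression(g1, cfg)
  expect_identical(e1, simulate_expression(g2, cfg))
  # distinct samples are distinct draws
  expect_false(identical(
    t1$tags, simulate_chip_tags(g1, cfg, "control", "input")$tags))
})

test_that("gene placement respects the genome and fails by pigeonhole", {
  cfg <- sim_config(seed = 3, n_genes = 0, n_cpgi = 30,
                    chrom_length = 2e5, depth = 1e4,
                    n_direct_targets = 0, n_bound_unchanged = 0)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$cpgi), 30)

  cfg_bad <- sim_config(seed = 3, n_chroms = 1, chrom_length = 1e6,
                        n_genes = 1000, gene_length = c(10000, 10000),
                        n_direct_targets = 0, n_bound_unchanged = 0)
  expect_error(simulate_genome(cfg_bad), "larger genome")

  # placed genes never overlap and stay in bounds
  cfg2 <- sim_config(seed = 5, n_genes = 200, chrom_length = 2e6,
                     n_direct_targets = 20, n_bound_unchanged = 5)
  g2 <- simulate_genome(cfg2)
  for (ch in names(g2$chrom_sizes)) {
    gg <- g2$genes[g2$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    expect_true(all(gg$end <= g2$chrom_sizes[[ch]]))
  }
})

test_that("tag rates match the Poisson oracle inside and outside islands", {
  # lambda_bg = depth / genome = 1000 / 1e5 = 0.01/bp; one 1-kb island at 10x
  sizes <- chrom_sizes(c(chr1 = 1e5))
  island <- tibble::tibble(chrom = "chr1", start = 50000L, end = 51000L,
                           fold = 10)
  genome <- bare_genome(sizes)
  n_in <- n_tot <- numeric(100)
  for (s in seq_len(100)) {
    cfg <- sim_config(seed = s, n_chroms = 1, chrom_length = 1e5,
                      depth = 1000, n_genes = 0, n_cpgi = 0,
                      n_direct_targets = 0, n_bound_unchanged = 0)
    ts <- simulate_chip_tags(genome, cfg, "treatment", "chip",
                             enriched = island)
    n_in[s] <- sum(ts$tags$pos >= 50000 & ts$tags$pos < 51000)
    n_tot[s] <- ts$n_tags
  }
  # expected 100 in-island (10 * 0.01 * 1000), 1090 total
  expect_lt(abs(mean(n_in) - 100), 3 * sd(n_in) / sqrt(100))
  expect_lt(abs(mean(n_tot) - 1090), 3 * sd(n_tot) / sqrt(100))
})

test_that("background window counts have Poisson moments", {
  cfg <- sim_config(seed = 9, n_chroms = 1, chrom_length = 1e6,
                    depth = 5e4, n_genes = 0, n_cpgi = 0,
                    n_direct_targets = 0, n_bound_unchanged = 0)
  genome <- bare_genome(chrom_sizes(c(chr1 = 1e6)))
  ts <- simulate_chip_tags(genome, cfg, "control", "input")
  wc <- count_window_tags(ts, genome$chrom_sizes, window = 200)
  cnt <- wc$chr1
  lam <- 5e4 * 200 / 1e6  # 10 per window
  n <- length(cnt)
  expect_lt(abs(mean(cnt) - lam), 3 * sqrt(lam / n))
  # Poisson variance == mean; sampling sd of the variance ~ lam*sqrt(2/n)
  expect_lt(abs(stats::var(cnt) - lam), 4 * lam * sqrt(2 / n))
})

test_that("expression draws recover the planted mean ratio as phi -> 0", {
  sizes <- chrom_sizes(c(chr1 = 1e5))
  genes <- validate_genes(tibble::tibble(
    gene_id = c("a", "b"), chrom = "chr1", strand = "+",
    start = c(1000L, 50000L), end = c(3000L, 52000L),
    exon_starts = list(1000L, 50000L), exon_ends = list(3000L, 52000L)))
  genome <- list(chrom_sizes = sizes, genes = genes,
                 truth = list(fold_changes = tibble::tibble(
                   gene_id = "a", fold = 2)))
  ratios <- numeric(100)
  for (s in seq_len(100)) {
    cfg <- sim_config(seed = s, expression_mean = 1000, dispersion = 1e-6,
                      n_genes = 2, n_direct_targets = 0,
                      n_bound_unchanged = 0)
    e <- simulate_expression(genome, cfg)
    ratios[s] <- e$count_KO[1] / e$count_WT[1]
  }
  expect_lt(abs(mean(ratios) - 0.5), 3 * sd(ratios) / sqrt(100))
  expect_error(
    simulate_expression(genome, sim_config(seed = 1),
                        fold_changes = tibble::tibble(gene_id = "a",
                                                      fold = -2)),
    "fold")
})

test_that("planted truth satisfies the direct-target rule by construction", {
  for (s in c(2, 17)) {
    cfg <- sim_config(seed = s)
    g <- simulate_genome(cfg)
    tr <- g$truth
    expect_equal(length(tr$direct_targets), cfg$n_direct_targets)
    expect_true(all(abs(tr$fold_changes$log2fc_true) >= 1))
    # each direct target owns a planted island inside its extended gene body
    ext <- extended_gene_body(g$genes, 10000, g$chrom_sizes)
    for (gid in tr$direct_targets) {
      isl <- tr$enriched[tr$enriched$gene_id == gid, ]
      e <- ext[ext$gene_id == gid, ]
      expect_equal(nrow(isl), 1)
      expect_true(isl$start < e$end && isl$end > e$start)
    }
    # planted intervals lie within the genome
    expect_true(all(tr$enriched$start >= 0))
    expect_true(all(tr$enriched$end <=
                      g$chrom_sizes[tr$enriched$chrom]))
  }
})
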