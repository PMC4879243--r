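test_that("window counting assigns shifted tags and conserves totals", {
  cs <- chrom_sizes(c(chr1 = 1000))
  wc <- count_window_tags(make_tags("chr1", 250L), cs, window = 200)
  expect_equal(wc$chr1, c(0L, 1L, 0L, 0L, 0L))

  # minus-strand tag at 199 shifted 75 bp 3'-ward lands at 124 -> window 0
  wc2 <- count_window_tags(make_tags("chr1", 199L, "-"), cs,
                           window = 200, shift = 75)
  expect_equal(which(wc2$chr1 == 1L), 1L)
  # plus-strand shift moves the other way
  wc3 <- count_window_tags(make_tags("chr1", 199L, "+"), cs,
                           window = 200, shift = 75)
  expect_equal(which(wc3$chr1 == 1L), 2L)

  set.seed(4)
  cs2 <- chrom_sizes(c(chr1 = 1e5, chr2 = 5e4))
  ts <- make_tags(sample(c("chr1", "chr2"), 1e4, TRUE),
                  sample.int(5e4, 1e4, TRUE) - 1L,
                  sample(c("+", "-"), 1e4, TRUE))
  wc4 <- count_window_tags(ts, cs2, window = 200, shift = 100)
  expect_equal(sum(wc4$chr1) + sum(wc4$chr2), 1e4)
  expect_equal(attr(wc4, "lambda"), 1e4 * 200 / 1.5e5)
})

test_that("Poisson upper tail and eligibility threshold are exact", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(round(poisson_upper_tail(3, 1), 4), 0.0803)
  expect_equal(poisson_upper_tail(1, 2), 1 - exp(-2))
  expect_true(all(diff(poisson_upper_tail(0:20, 4)) <= 0))
  expect_error(poisson_upper_tail(-1, 1), ">= 0")

  expect_equal(eligible_threshold(1, 0.2), 3L)
  expect_equal(eligible_threshold(1, 0.5), 2L)
  expect_equal(eligible_threshold(1, 0.999), 1L)
})

test_that("island aggregation follows the gap rule and sums window scores", {
  cs <- chrom_sizes(c(chr1 = 1200))
  # eligible windows (count 5) at [0,200) and [400,600); lambda 1, l0 3
  ts <- make_tags("chr1", c(rep(10L, 5), rep(410L, 5)))
  wc <- count_window_tags(ts, cs, window = 200)
  one <- build_islands(wc, l0 = 3L, gap = 200L, lambda = 1)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0L, 600L))
  expect_equal(one$score, -2 * log(poisson_upper_tail(5, 1)))

  two <- build_islands(wc, l0 = 3L, gap = 0L, lambda = 1)
  expect_equal(nrow(two), 2)
  expect_equal(two$end - two$start, c(200L, 200L))

  none <- build_islands(wc, l0 = 6L, gap = 200L, lambda = 1)
  expect_equal(nrow(none), 0)
})

test_that("island significance matches the Poisson survival oracle", {
  cs <- chrom_sizes(c(chr1 = 1e4))
  island <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L)
  chip <- make_tags("chr1", sample.int(1000, 100, TRUE) + 999L, id = "chip")
  ctrl10 <- make_tags("chr1", c(sample.int(1000, 10, TRUE) + 999L,
                                sample.int(7000, 90, TRUE) + 2499L),
                      id = "ctrl")
  sig <- island_significance(island, chip, ctrl10, cs)
  expect_equal(sig$n_chip, 100L)
  expect_equal(sig$n_ctrl, 10L)
  expect_equal(sig$p_value, poisson_upper_tail(100, 10))

  # zero chip count: p = 1
  empty_chip <- make_tags("chr1", 5000L, id = "chip0")
  expect_equal(
    island_significance(island, empty_chip, ctrl10, cs)$p_value, 1)

  # equal counts at equal depth sit near the Poisson median
  chip_eq <- make_tags("chr1", sample.int(1000, 50, TRUE) + 999L)
  ctrl_eq <- make_tags("chr1", sample.int(1000, 50, TRUE) + 999L)
  p_eq <- island_significance(island, chip_eq, ctrl_eq, cs)$p_value
  expect_gt(p_eq, 0.4)
  expect_lt(p_eq, 0.7)
})

test_that("self-comparison yields no significant islands", {
  set.seed(21)
  cs <- chrom_sizes(c(chr1 = 2e5))
  pos <- sample.int(2e5, 5000, TRUE) - 1L
  chip <- make_tags("chr1", pos, id = "chip")
  ctrl <- make_tags("chr1", pos, id = "ctrl")
  isl <- call_islands(chip, ctrl, caller_params(), cs)
  expect_equal(nrow(isl), 0)
})

test_that("caller matches a brute-force enumerator on tiny inputs", {
  set.seed(31)
  cs <- chrom_sizes(c(chr1 = 10000))
  w <- 200L
  for (rep in 1:5) {
    pos <- sample.int(10000, 400, TRUE) - 1L
    # spike three windows so candidates exist
    pos <- c(pos, rep(1010L, 15), rep(1410L, 12), rep(8050L, 20))
    chip <- make_tags("chr1", pos, id = "chip")
    wc <- count_window_tags(chip, cs, window = w)
    lambda <- attr(wc, "lambda")
    l0 <- eligible_threshold(lambda, 0.2)
    got <- build_islands(wc, l0, gap = w, lambda)

    # oracle: direct scan over windows merging eligible runs with <= 1
    # ineligible window between them
    cnt <- wc$chr1
    elig <- cnt >= l0
    want <- list()
    i <- 1
    while (i <= length(cnt)) {
      if (elig[i]) {
        j <- i
        last_elig <- i
        while (j < length(cnt)) {
          nxt <- which(elig & seq_along(elig) > j)
          if (!length(nxt) || (nxt[1] - last_elig - 1) * w > w) break
          j <- nxt[1]; last_elig <- j
        }
        want[[length(want) + 1]] <- c(i, last_elig)
        i <- last_elig + 1
      } else i <- i + 1
    }
    want <- do.call(rbind, want)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, (want[, 1] - 1L) * w)
    expect_equal(got$end, want[, 2] * w)
    # score additivity, exact
    for (k in seq_len(nrow(got))) {
      idx <- want[k, 1]:want[k, 2]
      sc <- sum(-log(poisson_upper_tail(cnt[idx][elig[idx]], lambda)))
      expect_equal(got$score[k], sc)
    }
  }
})

test_that("planted islands are recovered and alpha is monotone", {
  cfg <- sim_config(seed = 6, chrom_length = 2e6, n_genes = 100,
                    depth = 8e4, n_direct_targets = 10,
                    n_bound_unchanged = 2, n_cpgi = 40)
  g <- simulate_genome(cfg)
  chip <- simulate_chip_tags(g, cfg, "treatment", "chip")
  ctrl <- simulate_chip_tags(g, cfg, "control", "ko")
  inp <- simulate_chip_tags(g, cfg, "control", "input")
  isl <- call_islands(chip, list(ctrl, inp), caller_params(), g$chrom_sizes)
  st <- island_recovery_stats(isl, g$truth$enriched)
  expect_gte(st$recall, 0.9)
  expect_gte(st$precision, 0.9)

  # lowering alpha never adds islands
  strict <- call_islands(chip, list(ctrl, inp),
                         caller_params(fdr = 1e-8), g$chrom_sizes)
  loose <- call_islands(chip, list(ctrl, inp),
                        caller_params(fdr = 1e-3), g$chrom_sizes)
  key <- function(x) paste(x$chrom, x$start, x$end)
  expect_true(all(key(strict) %in% key(isl)))
  expect_true(all(key(isl) %in% key(loose)))

  # pooled mode also recovers the planted set
  pooled <- call_islands(chip, list(ctrl, inp),
                         caller_params(control_mode = "pooled"),
                         g$chrom_sizes)
  expect_gte(island_recovery_stats(pooled, g$truth$enriched)$recall, 0.9)
})
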