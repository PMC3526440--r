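test_that("locus score is the negative log-sum of branch p-values", {
  expect_equal(locus_score(c(1, 1, 1)), 0)
  expect_equal(locus_score(c(0.1, 0.01)), log(1000))
  expect_true(is.na(locus_score(numeric(0))))
  # replacing a p-value by a larger one strictly decreases the score
  base <- c(0.2, 0.05, 0.5)
  expect_lt(locus_score(c(0.2, 0.30, 0.5)), locus_score(base))
  expect_error(locus_score(c(0.5, 0)), "pvalues > 0")
})

test_that("a degenerate single-branch cell yields a point-mass null at zero", {
  degen <- transition_table(tibble::tibble(
    a = 2, lambda_min = 0, lambda_max = 0, prob = list(c(0, 0, 1))))
  null <- null_distribution(degen, tibble::tibble(lambda = 0, a = 2))
  expect_equal(sum(null$mass), 1)
  expect_equal(null$mass[1L], 1) # all mass in the zero-score bin
  expect_equal(locus_significance(0, null), 1)
})

test_that("the single-branch toy null carries the enumerated masses", {
  toy <- toy_table()
  null <- null_distribution(toy, tibble::tibble(lambda = 10, a = 2),
                            bin_width = 0.05)
  # outcomes b = 0..3 have tail p-values 1, 0.5, 0.2, 0.05 and thus scores
  # 0, 0.693, 1.609, 2.996 with masses 0.5, 0.3, 0.15, 0.05
  expect_equal(sum(null$mass), 1)
  bins <- floor(c(0, -log(0.5), -log(0.2), -log(0.05)) / 0.05 + 1e-9) + 1L
  expect_equal(null$mass[bins], c(0.5, 0.3, 0.15, 0.05))
  expect_equal(sum(null$mass[-bins]), 0)
  # tail of the enumerated null at the observed b = 2 score
  expect_equal(locus_significance(-log(0.2), null), 0.20)
  expect_equal(locus_significance(0, null), 1)
  # beyond the support: floored at the smallest positive mass, never 0
  expect_equal(locus_significance(50, null), 0.05)
})

test_that("convolved nulls match Monte-Carlo sampling of branch outcomes", {
  set.seed(31)
  for (rep in 1:3) {
    # randomized 3-branch toy tables
    cells <- lapply(1:3, function(i) {
      pr <- stats::rgamma(sample(3:6, 1), 1); pr / sum(pr)
    })
    tab <- transition_table(tibble::tibble(
      a = 1:3, lambda_min = 10 * (1:3), lambda_max = 10 * (1:3),
      prob = cells))
    conds <- tibble::tibble(lambda = 10 * (1:3), a = 1:3)
    null <- null_distribution(tab, conds, bin_width = 0.05)
    expect_equal(sum(null$mass), 1, tolerance = 1e-9)
    # Monte Carlo: draw outcomes per branch, discretise each branch score on
    # the same bin grid the convolution uses, sum the bin indices
    n_mc <- 1e5
    total_bin <- rowSums(vapply(1:3, function(j) {
      pr <- cells[[j]]
      bs <- sample(seq_along(pr) - 1L, n_mc, replace = TRUE, prob = pr)
      scores <- vapply(seq_along(pr) - 1L, function(b) {
        -log(sum(pr[(seq_along(pr) - 1L) >= b]))
      }, numeric(1))
      floor(scores / 0.05 + 1e-9)[bs + 1L]
    }, numeric(n_mc)))
    mc_cdf <- cumsum(tabulate(total_bin + 1L, nbins = length(null$mass))) / n_mc
    exact_cdf <- cumsum(null$mass)
    expect_lt(max(abs(mc_cdf - exact_cdf)), 0.01) # KS distance on the bin grid
  }
})

test_that("halving the bin width changes p-values by at most one bin's mass", {
  toy <- toy_table()
  conds <- tibble::tibble(lambda = c(10, 10), a = c(2, 2))
  n1 <- null_distribution(toy, conds, bin_width = 0.05)
  n2 <- null_distribution(toy, conds, bin_width = 0.025)
  for (s in c(0.5, 1.0, 1.61, 3.0, 4.6)) {
    p1 <- locus_significance(s, n1)
    p2 <- locus_significance(s, n2)
    biggest_bin <- max(n1$mass)
    expect_lte(p2 - p1, biggest_bin + 1e-12)
    expect_gte(p1 - p2, -1e-12) # coarser binning is the more conservative
  }
})

test_that("scan_loci is deterministic and respects both threshold modes", {
  phy <- example_tree()
  p <- calibrate_threshold(synthetic_pwm(8, 10), seed = 4)
  sim <- simulate_blocks(phy, n_blocks = 25, block_len = 250, seed = 21)
  w <- extract_windows(sim$blocks, phy, window_size = 200)
  tab <- estimate_table(w, phy, p, min_obs = 20L)
  l1 <- scan_loci(sim$blocks, phy, p, tab, step = 100, alpha = 0.3)
  l2 <- scan_loci(sim$blocks, phy, p, tab, step = 100, alpha = 0.3)
  expect_identical(tidy(l1), tidy(l2))
  expect_identical(locus_sites(l1), locus_sites(l2))
  # score-threshold mode flags exactly the windows at or above the cutoff
  thr <- stats::quantile(l1$score, 0.8, na.rm = TRUE)
  l3 <- scan_loci(sim$blocks, phy, p, tab, step = 100, score_threshold = thr)
  expect_equal(l3$significant, !is.na(l3$score) & l3$score >= thr)
  # member sites lie inside their windows and carry the right width
  st <- locus_sites(l1)
  if (nrow(st) > 0L) {
    win <- tidy(l1)
    m <- match(st$window_id, win$window_id)
    expect_true(all(st$start >= win$start[m] & st$end <= win$end[m]))
    expect_true(all(st$end - st$start == p$width))
  }
})

test_that("perfectly conserved alignments yield no surprising conservation", {
  phy <- example_tree()
  p <- calibrate_threshold(synthetic_pwm(8, 10), seed = 4)
  # training data holds both diverged and perfectly conserved windows, as a
  # genome-wide estimation would
  sim <- simulate_blocks(phy, n_blocks = 30, block_len = 250, seed = 22)
  frozen <- sim$blocks
  for (i in seq_len(nrow(frozen))) {
    rows <- frozen$rows[[i]]
    ref_row <- gsub("[-.]", "", rows[[frozen$ref[i]]])
    frozen$rows[[i]] <- stats::setNames(rep(list(ref_row), length(rows)),
                                        names(rows)) |> unlist()
    frozen$ref_start[i] <- frozen$ref_start[i] + 100000L
    frozen$ref_end[i] <- frozen$ref_start[i] + nchar(ref_row)
    frozen$block_id[i] <- frozen$block_id[i] + 1000L
  }
  both <- bindingloci:::new_block_set(dplyr::bind_rows(sim$blocks, frozen))
  w <- extract_windows(both, phy, window_size = 200)
  tab <- estimate_table(w, phy, p, min_obs = 20L)
  lz <- scan_loci(frozen, phy, p, tab, step = 200, alpha = 0.05)
  # every branch has lambda = 0 and b = a; p-values near 1, no significance
  expect_true(all(!lz$significant))
  expect_true(all(lz$null_pvalue[!is.na(lz$null_pvalue)] > 0.5))
})

test_that("merged runs cover overlapping significant windows with best scores", {
  loci <- tibble::tibble(
    window_id = 1:6, chrom = "c1",
    start = c(0L, 20L, 40L, 200L, 400L, 420L),
    end = start + 100L,
    n_branches = 5L,
    score = c(5, 9, 6, 2, 4, 3),
    null_pvalue = c(.01, .001, .01, .5, .02, .03),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  runs <- bindingloci:::merge_significant(loci)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$start, c(0L, 400L))
  expect_equal(runs$end, c(140L, 520L))
  expect_equal(runs$score, c(9, 4))
  expect_equal(runs$null_pvalue, c(0.001, 0.02))
  expect_equal(runs$n_windows, c(3L, 2L))
})
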