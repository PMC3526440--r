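test_that("count matrices normalise to column-stochastic probabilities", {
  counts <- matrix(0, 4, 4)
  diag(counts) <- 10
  p0 <- pwm(counts, pseudocount = 0)
  expect_equal(unname(p0$mat), diag(4))
  p1 <- pwm(counts, pseudocount = 0.1)
  expect_equal(unname(p1$mat[1, 1]), 10.1 / 10.4)
  expect_equal(unname(p1$mat[2, 1]), 0.1 / 10.4)
  expect_true(all(abs(colSums(p1$mat) - 1) < 1e-9))
  expect_true(all(p1$mat > 0))
})

test_that("degenerate and undersized matrices are rejected", {
  expect_error(pwm(matrix(1, 4, 3)), "width")
  expect_error(pwm(matrix(0, 4, 4), pseudocount = 0), "all-zero")
  expect_error(pwm(matrix(-1, 4, 4)), "negative")
})

test_that("information content matches closed forms", {
  unif <- pwm(matrix(1, 4, 6), pseudocount = 0)
  expect_equal(information_content(unif), 0)
  det9 <- pwm(diag(4)[, rep(1:4, length.out = 9)], pseudocount = 0)
  expect_equal(information_content(det9), 18) # 2 bits per deterministic column
  # non-uniform background: hand-summed on a 4-column matrix
  m <- matrix(c(.7, .1, .1, .1), 4, 4)
  bgv <- background(c(.4, .1, .1, .4))
  expect_equal(information_content(pwm(m, pseudocount = 0), bgv),
               4 * sum(c(.7, .1, .1, .1) * log2(c(.7, .1, .1, .1) / bgv)))
})

test_that("synthetic_pwm hits its information-content target", {
  for (bits in c(8, 10, 18)) {
    sp <- synthetic_pwm(10, bits)
    expect_equal(information_content(sp), bits, tolerance = 1e-6)
  }
})

test_that("llr_score matches hand-computed sums", {
  p <- pwm(matrix(c(8, 1, 1, 1), 4, 4), pseudocount = 0, id = "flatcons")
  # all columns identical, consensus A
  expect_equal(llr_score("AAAA", p), 4 * log((8 / 11) / 0.25))
  # matrix equal to the background scores zero on any sequence
  unif <- pwm(matrix(1, 4, 4), pseudocount = 0)
  expect_equal(llr_score("ACGT", unif), 0)
  expect_equal(llr_score("GGGG", unif), 0)
  # hand-built 4-column matrix vs brute-force sum of log terms
  m <- matrix(c(.5, .2, .2, .1,
                .1, .6, .2, .1,
                .25, .25, .25, .25,
                .05, .05, .45, .45), nrow = 4)
  p2 <- pwm(m, pseudocount = 0)
  expect_equal(llr_score("ACGT", p2),
               log(.5 / .25) + log(.6 / .25) + log(.25 / .25) + log(.45 / .25))
  expect_error(llr_score("ACG", p2), "length")
  expect_error(llr_score("ACNT", p2), "non-ACGT")
})

test_that("scan reports strict-exceed hits on both strands with unique (offset, strand)", {
  p <- pwm(diag(4)[, c(1, 2, 3, 4, 4)] * 9, pseudocount = 0.01, id = "acgtt")
  cons <- "ACGTT"
  seqc <- paste0("TTTTT", cons, "GG", reverse_complement(cons), "GG")
  hits <- scan_pwm(seqc, p, threshold = 5)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$start[hits$strand == "+"], 5L)
  expect_equal(hits$start[hits$strand == "-"], 12L)
  expect_false(any(duplicated(hits[, c("start", "strand")])))
  # shorter-than-width input
  expect_equal(nrow(scan_pwm("ACG", p, threshold = 0)), 0L)
})

test_that("scanning is strand-symmetric and monotone in the threshold", {
  p <- random_pwm(7, seed = 11)
  for (s in 1:5) {
    seqc <- random_dna(300, seed = 100 + s)
    fwd <- scan_pwm(seqc, p, threshold = 0)
    rev <- scan_pwm(reverse_complement(seqc), p, threshold = 0)
    expect_equal(sort(fwd$llr), sort(rev$llr))
    # offsets mirror: start' = L - w - start, strands swap
    expect_setequal(
      paste(300 - p$width - fwd$start, ifelse(fwd$strand == "+", "-", "+")),
      paste(rev$start, rev$strand))
    counts <- vapply(c(-2, 0, 2, 4),
                     function(th) count_sites(seqc, p, threshold = th),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("windows overlapping ambiguous bases are skipped", {
  p <- random_pwm(5, seed = 2)
  seqc <- "ACGTACGTNNACGTACGT"
  hits <- scan_pwm(seqc, p, threshold = -100)
  # every offset whose window covers an N is absent
  bad <- 4:9 # 0-based starts overlapping positions 8,9 (0-based)
  expect_true(all(!hits$start %in% bad))
  # both strands present for all clean offsets at a permissive threshold
  clean <- setdiff(0:(nchar(seqc) - 5), bad)
  expect_equal(nrow(hits), 2L * length(clean))
})

test_that("scan and count match the naive oracle scorer exactly", {
  p <- random_pwm(8, seed = 5)
  for (s in 1:20) {
    seqc <- random_dna(150, seed = 7000 + s)
    got <- scan_pwm(seqc, p, threshold = 1.5)
    want <- naive_scan(seqc, p, threshold = 1.5)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start[order(want$start, want$strand)])
    expect_equal(got$llr, want$llr[order(want$start, want$strand)],
                 tolerance = 1e-12)
    expect_identical(count_sites(seqc, p, threshold = 1.5), nrow(want))
  }
})

test_that("threshold calibration follows the nearest-rank 10th-percentile law", {
  p <- random_pwm(9, seed = 3)
  cal <- calibrate_threshold(p, n_samples = 1000L, percentile = 10, seed = 42)
  # regenerate the same samples and check the construction law: 900 strictly above
  lmat <- log(p$mat / 0.25)
  scores <- withr::with_seed(42, {
    draws <- vapply(seq_len(9), function(j) {
      sample.int(4L, 1000L, replace = TRUE, prob = p$mat[, j])
    }, integer(1000))
    rowSums(matrix(lmat[cbind(as.vector(draws), rep(1:9, each = 1000))], nrow = 1000))
  })
  expect_equal(cal$threshold, sort(scores)[100])
  expect_equal(sum(scores > cal$threshold), 900L)
})

test_that("calibration is deterministic given the seed and warns on tie degeneracy", {
  p <- random_pwm(6, seed = 9)
  t1 <- calibrate_threshold(p, seed = 7)$threshold
  t2 <- calibrate_threshold(p, seed = 7)$threshold
  expect_identical(t1, t2)
  expect_false(identical(t1, calibrate_threshold(p, seed = 8)$threshold))
  det <- pwm(diag(4)[, c(1, 2, 3, 4)] * 10, pseudocount = 0)
  expect_warning(cald <- calibrate_threshold(det, seed = 1), "identically")
  # all samples are the consensus: none strictly exceeds the threshold
  expect_equal(count_sites("ACGT", cald), 0L)
})

test_that("calibrated threshold approximates the exact discrete quantile", {
  # 4-column PWM small enough to enumerate all 256 sequences exactly
  m <- matrix(c(.5, .2, .2, .1,
                .4, .3, .2, .1,
                .6, .2, .1, .1,
                .3, .3, .2, .2), nrow = 4)
  p <- pwm(m, pseudocount = 0)
  lmat <- log(p$mat / 0.25)
  grid <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  sc <- vapply(seq_len(nrow(grid)), function(i) {
    sum(lmat[cbind(grid[i, ], 1:4)])
  }, numeric(1))
  pr <- vapply(seq_len(nrow(grid)), function(i) {
    prod(p$mat[cbind(grid[i, ], 1:4)])
  }, numeric(1))
  cal <- calibrate_threshold(p, n_samples = 1000L, seed = 5)
  # mass of the exact enumeration strictly above the sampled threshold:
  # should be ~0.90 within Monte-Carlo (binomial) error
  exact_tail <- sum(pr[sc > cal$threshold])
  expect_lt(abs(exact_tail - 0.90), 3 * sqrt(0.1 * 0.9 / 1000) + 0.02)
})
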