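# Hand-built window tibbles let us control (lambda, a, b) triples exactly.
manual_windows <- function(rowsets, ref = "hg") {
  tibble::tibble(
    window_id = seq_along(rowsets),
    block_id = seq_along(rowsets), chrom = "chrT",
    start = 0L, end = nchar(gsub("-", "", rowsets[[1L]][[ref]])),
    rows = rowsets,
    seqs = lapply(rowsets, function(r) vapply(r, function(x) gsub("-", "", x),
                                              character(1))),
    missing = list(character(0))
  )
}

two_leaf_tree <- function() {
  phylogeny(ape::read.tree(text = "(hg:1,mm:1)root;"), reference = "hg")
}

# Sequence with exactly n non-overlapping consensus hits of `p` and no
# accidental ones: consensus blocks separated by long T runs.
planted_seq <- function(p, n, len = 120L) {
  cons <- paste(c("A", "C", "G", "T")[apply(p$mat, 2, which.max)], collapse = "")
  body <- paste(rep(c(cons, strrep("T", 12)), n), collapse = "")
  paste0(strrep("T", 10), body, strrep("T", max(0L, len - nchar(body) - 10L)))
}

strong_pwm <- function() {
  # consensus ACGCA; T-runs can't hit it on either strand
  pwm(diag(4)[, c(1, 2, 3, 2, 1)] * 12, pseudocount = 0.01, id = "strong",
      threshold = 4)
}

test_that("identical parent and child rows give a point mass at b = a", {
  phy <- two_leaf_tree()
  p <- strong_pwm()
  rowsets <- lapply(1:6, function(i) {
    s <- planted_seq(p, n = (i %% 3) + 1L)
    c(hg = s, mm = s, root = s)
  })
  tab <- estimate_table(manual_windows(rowsets), phy, p,
                        min_obs = 1L, smooth = 0)
  flat <- tidy(tab)
  expect_true(all(flat$lambda_min == 0 & flat$lambda_max == 0))
  for (a in unique(flat$a)) {
    expect_equal(transition_prob(tab, 0, a, a), 1)
    expect_equal(branch_pvalue(tab, 0, a, a), 1) # preservation is no surprise
  }
})

test_that("hand-chosen divergent branches estimate exact empirical fractions", {
  phy <- two_leaf_tree()
  p <- strong_pwm()
  parent <- planted_seq(p, 2, len = 200L)
  # child 1 loses one site; child 2 keeps both; both diverge ~10%
  mut10 <- function(s, keep_sites = TRUE) {
    ch <- strsplit(s, "")[[1L]]
    tpos <- which(ch == "T")
    flip <- tpos[seq(1, length(tpos), length.out = round(nchar(s) / 10))]
    ch[flip] <- "G"
    paste(ch, collapse = "")
  }
  kill_one <- function(s) sub("ACGCA", "TTTTT", s) # destroys first planted site
  child_keep <- mut10(parent)
  child_lose <- mut10(kill_one(parent))
  lam_keep <- divergence(parent, child_keep)
  lam_lose <- divergence(parent, child_lose)
  rowsets <- list(c(hg = child_keep, root = parent),
                  c(hg = child_lose, root = parent))
  tab <- estimate_table(manual_windows(rowsets), phy, p,
                        min_obs = 1L, smooth = 0)
  expect_equal(count_sites(parent, p), 2L)
  expect_equal(count_sites(child_keep, p), 2L)
  expect_equal(count_sites(child_lose, p), 1L)
  # both observations share a pooled cell iff lambdas are close; force pooling
  tab_pooled <- estimate_table(manual_windows(rowsets), phy, p,
                               min_obs = 2L, smooth = 0)
  expect_equal(transition_prob(tab_pooled, lam_keep, 2, 2), 0.5)
  expect_equal(transition_prob(tab_pooled, lam_lose, 2, 1), 0.5)
})

test_that("every populated cell normalises to one, with and without smoothing", {
  phy <- example_tree()
  p <- calibrate_threshold(synthetic_pwm(8, 10), seed = 4)
  sim <- simulate_blocks(phy, n_blocks = 40, block_len = 250, seed = 11)
  w <- extract_windows(sim$blocks, phy, window_size = 200)
  for (fl in c(0, 0.5)) {
    tab <- estimate_table(w, phy, p, min_obs = 20L, smooth = fl)
    sums <- vapply(tab$cells$prob, sum, numeric(1))
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(vapply(tab$cells$count, function(x) all(x >= 0), logical(1))))
  }
})

test_that("pooling merges sparse divergence bins up to the minimum count", {
  phy <- example_tree()
  p <- calibrate_threshold(synthetic_pwm(8, 10), seed = 4)
  sim <- simulate_blocks(phy, n_blocks = 60, block_len = 250, seed = 12)
  w <- extract_windows(sim$blocks, phy, window_size = 200)
  tab <- estimate_table(w, phy, p, min_obs = 50L)
  cells <- tab$cells
  # every pool but possibly the last one per `a` meets the minimum
  for (a in unique(cells$a)) {
    sub <- cells[cells$a == a, ]
    if (nrow(sub) > 1L) expect_true(all(sub$n_obs >= 50L))
    # pools are ordered and non-overlapping in lambda
    expect_true(all(diff(sub$lambda_min) > 0))
    expect_true(all(sub$lambda_max[-nrow(sub)] < sub$lambda_min[-1L]))
  }
})

test_that("branch p-values are exact tail sums on the toy cell", {
  toy <- toy_table()
  expect_equal(branch_pvalue(toy, 10, 2, 2), 0.20)
  expect_equal(branch_pvalue(toy, 10, 2, 3), 0.05)
  expect_equal(branch_pvalue(toy, 10, 2, 1), 0.50)
  expect_equal(branch_pvalue(toy, 10, 2, 0), 1.00)
  # non-increasing in b, equal to 1 at b = 0
  pv <- vapply(0:3, function(b) branch_pvalue(toy, 10, 2, b), numeric(1))
  expect_true(all(diff(pv) <= 0))
  expect_equal(pv[1L], 1)
})

test_that("the literal tail orientation is exposed but distinct", {
  toy <- toy_table()
  # literal: tail over b' >= 2a - b ; at a=2, b=1 -> b' >= 3 -> 0.05
  expect_equal(branch_pvalue(toy, 10, 2, 1, literal = TRUE), 0.05)
  # perfect preservation under the literal reading: b' >= 2 -> 0.20
  expect_equal(branch_pvalue(toy, 10, 2, 2, literal = TRUE), 0.20)
  expect_false(branch_pvalue(toy, 10, 2, 1, literal = TRUE) ==
                 branch_pvalue(toy, 10, 2, 1))
})

test_that("unsupported conditions raise a catchable signal", {
  toy <- toy_table()
  expect_error(branch_pvalue(toy, 10, 7, 1), class = "bindingloci_unsupported")
  expect_error(transition_prob(toy, 10, 7, 1), class = "bindingloci_unsupported")
  # nearest pool is used for lambdas outside any range
  expect_equal(branch_pvalue(toy, 99, 2, 2), 0.20)
})

test_that("additive smoothing gives unseen child counts mass near 0.5/n", {
  phy <- two_leaf_tree()
  p <- strong_pwm()
  s <- planted_seq(p, 2, len = 200L)
  rowsets <- lapply(1:5, function(i) c(hg = s, root = s))
  tab <- estimate_table(manual_windows(rowsets), phy, p,
                        min_obs = 1L, smooth = 0.5)
  # 5 observations (only the hg branch has data), all with b = a = 2;
  # support is 0..4, so Pr[2] = 5.5 / 7.5 and each unseen b gets 0.5 / 7.5
  expect_equal(transition_prob(tab, 0, 2, 2), 5.5 / 7.5)
  expect_equal(transition_prob(tab, 0, 2, 0), 0.5 / 7.5)
  expect_equal(transition_prob(tab, 0, 2, 4), 0.5 / 7.5)
  expect_equal(transition_prob(tab, 0, 2, 40), 0) # beyond smoothed support
})

test_that("transition tables round-trip through their text serialisation", {
  phy <- example_tree()
  p <- calibrate_threshold(synthetic_pwm(8, 10), seed = 4)
  sim <- simulate_blocks(phy, n_blocks = 30, block_len = 250, seed = 13)
  w <- extract_windows(sim$blocks, phy, window_size = 200)
  tab <- estimate_table(w, phy, p, min_obs = 20L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_transition_table(tab, f)
  back <- read_transition_table(f)
  expect_equal(back$a_cap, tab$a_cap)
  expect_equal(back$smooth, tab$smooth)
  expect_equal(back$threshold, tab$threshold)
  expect_equal(nrow(back$cells), nrow(tab$cells))
  # identical scoring behaviour on a grid of conditions
  flat <- tidy(tab)
  for (i in seq_len(min(nrow(flat), 40L))) {
    expect_equal(
      branch_pvalue(back, flat$lambda_min[i], flat$a[i], flat$b[i]),
      branch_pvalue(tab, flat$lambda_min[i], flat$a[i], flat$b[i]))
  }
})

test_that("capped counts pool into the cap bin", {
  phy <- two_leaf_tree()
  p <- strong_pwm()
  s <- planted_seq(p, 6, len = 200L)
  rowsets <- list(c(hg = s, root = s))
  expect_message(
    tab <- estimate_table(manual_windows(rowsets), phy, p, min_obs = 1L,
                          a_cap = 4L, smooth = 0),
    "cap bin")
  expect_equal(count_sites(s, p), 6L)
  expect_equal(transition_prob(tab, 0, 6, 6), 1) # both capped to 4
  expect_equal(branch_pvalue(tab, 0, 9, 9), 1)
})

test_that("re-simulated data fits the estimated table within multinomial error", {
  # a single fixed branch length keeps the divergence distribution identical
  # across the two runs, so pooled cells compare like with like
  phy <- phylogeny(ape::read.tree(text = "(hg:0.15,mm:0.15)root;"),
                   reference = "hg")
  p <- calibrate_threshold(synthetic_pwm(8, 10), seed = 4)
  simA <- simulate_blocks(phy, n_blocks = 500, block_len = 250, seed = 71)
  wA <- extract_windows(simA$blocks, phy, window_size = 200)
  tab <- estimate_table(wA, phy, p, min_obs = 50L, smooth = 0)
  simB <- simulate_blocks(phy, n_blocks = 500, block_len = 250, seed = 72)
  wB <- extract_windows(simB$blocks, phy, window_size = 200)
  obsB <- bindingloci:::observe_branches(wB, phy, p)
  obsB$a <- pmin(obsB$a, tab$a_cap); obsB$b <- pmin(obsB$b, tab$a_cap)
  tested <- 0L; rejected <- 0L
  for (i in seq_len(nrow(tab$cells))) {
    cell <- tab$cells[i, ]
    sel <- obsB$a == cell$a & obsB$lambda >= cell$lambda_min &
      obsB$lambda <= cell$lambda_max
    if (sum(sel) < 50L) next
    pr <- cell$prob[[1L]]
    bmax <- length(pr) - 1L
    x <- tabulate(pmin(obsB$b[sel], bmax) + 1L, nbins = bmax + 1L)
    # fold bins with tiny expectation into their neighbour for chi-square
    keep <- pr > 0
    pv <- suppressWarnings(stats::chisq.test(x[keep], p = pr[keep],
                                             rescale.p = TRUE))$p.value
    tested <- tested + 1L
    if (!is.na(pv) && pv < 0.01) rejected <- rejected + 1L
  }
  expect_gte(tested, 5L)
  expect_lte(rejected / tested, 0.05)
})
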