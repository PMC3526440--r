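# Combining per-branch p-values into a binding-locus score and assessing it
# against an exact (up to binning) null obtained by convolving the discrete
# per-branch score distributions.

#' Binding locus score
#'
#' Minus the sum of natural logs of the per-branch conditional p-values.
#' Branches skipped for missing data or unsupported conditions contribute
#' nothing; with no contributing branch the score is undefined.
#'
#' @param pvalues Numeric vector of per-branch p-values in (0, 1].
#' @return Non-negative score, or `NA` for an empty vector.
#' @export
#' @examples
#' locus_score(c(0.1, 0.01)) # log(1000)
locus_score <- function(pvalues) {
  if (length(pvalues) == 0L) return(NA_real_)
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  -sum(log(pvalues))
}

# Discrete distribution of one branch's score contribution -ln(pvalue),
# binned at `bin_width`, for the (pooled) cell of a condition. Returns a
# dense mass vector whose i-th element is the mass of bin index i-1
# (bin j covers scores in [j*bw, (j+1)*bw)).
branch_score_dist <- function(cell, a_capped, bin_width, literal = FALSE) {
  pr <- cell$prob[[1L]]
  support <- seq_along(pr) - 1L
  tails <- vapply(support, function(b) {
    cut <- if (literal) 2L * a_capped - b else b
    p <- sum(pr[support >= cut])
    if (p <= 0) p <- min(pr[pr > 0])
    min(p, 1)
  }, numeric(1))
  scores <- -log(tails)
  bins <- pmax(0L, as.integer(floor(scores / bin_width + 1e-9)))
  mass <- numeric(max(bins) + 1L)
  for (i in seq_along(bins)) mass[bins[i] + 1L] <- mass[bins[i] + 1L] + pr[i]
  mass
}

conv_dense <- function(m1, m2) {
  # exact discrete convolution; iterate over the sparser operand's support
  if (sum(m2 > 0) > sum(m1 > 0)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  n1 <- length(m1)
  out <- numeric(n1 + length(m2) - 1L)
  for (j in which(m2 > 0)) {
    idx <- j:(j + n1 - 1L)
    out[idx] <- out[idx] + m2[j] * m1
  }
  out
}

#' Null distribution of the binding locus score by convolution
#'
#' For each branch condition `(lambda, a)`, the neutral outcome `b` is drawn
#' from the transition table's cell; the branch contributes `-ln(pvalue)` of
#' that outcome. The locus score's null distribution is the convolution of
#' these independent discrete distributions, computed exactly up to binning
#' of scores at `bin_width`.
#'
#' @param table A `transition_table`.
#' @param conditions Tibble or data frame with columns `lambda` and `a`, one
#'   row per contributing branch.
#' @param bin_width Score bin width in `-ln p` units (default 0.05).
#' @param literal Passed to the branch p-value orientation; see
#'   [branch_pvalue()].
#' @param .dist_cache Optional environment memoising per-cell branch score
#'   distributions across calls (used internally by [scan_loci()]).
#' @return A `null_score_dist` object: list with `bin_width`, `mass` (dense
#'   vector over bin indices starting at 0) and `conditions`.
#' @export
null_distribution <- function(table, conditions, bin_width = 0.05,
                              literal = FALSE, .dist_cache = NULL) {
  stopifnot(nrow(conditions) >= 1L)
  mass <- 1
  for (j in seq_len(nrow(conditions))) {
    cell <- find_cell(table, conditions$lambda[j], conditions$a[j])
    if (is.null(cell)) {
      stop(unsupported_condition(conditions$lambda[j], conditions$a[j]))
    }
    a_cap <- min(conditions$a[j], table$a_cap)
    if (is.null(.dist_cache)) {
      bd <- branch_score_dist(cell, a_cap, bin_width, literal)
    } else {
      ck <- paste(cell$a, cell$lambda_min, cell$lambda_max, a_cap, sep = "_")
      bd <- .dist_cache[[ck]]
      if (is.null(bd)) {
        bd <- branch_score_dist(cell, a_cap, bin_width, literal)
        .dist_cache[[ck]] <- bd
      }
    }
    mass <- conv_dense(mass, bd)
  }
  structure(list(bin_width = bin_width,
                 mass = mass,
                 conditions = tibble::as_tibble(conditions)),
            class = "null_score_dist")
}

#' @export
print.null_score_dist <- function(x, ...) {
  cat(sprintf("<null_score_dist> %d branches, %d bins of width %g, total mass %.6f\n",
              nrow(x$conditions), length(x$mass), x$bin_width, sum(x$mass)))
  invisible(x)
}

# Pr[null bin-sum >= observed bin-sum] where the observed per-branch
# contributions are discretised on the same grid the null was built on.
# This is the internally consistent comparison: both sides truncate each
# branch's -ln p to its bin, so accumulated sub-bin remainders can never
# make an unsurprising window look significant.
locus_significance_binned <- function(pvalues, null) {
  bins <- floor(-log(pvalues) / null$bin_width + 1e-9)
  obs_bin <- sum(bins)
  if (obs_bin <= 0) return(1)
  idx <- seq_along(null$mass) - 1L
  p <- sum(null$mass[idx >= obs_bin])
  if (p <= 0) p <- min(null$mass[null$mass > 0])
  min(p, 1)
}

#' Significance of an observed locus score under the convolution null
#'
#' `Pr[null score >= observed]`, evaluated conservatively with bin upper
#' edges: all mass in any bin whose upper edge reaches the observed score is
#' counted. Never returns exactly zero; scores beyond the null's support are
#' floored at the smallest positive bin mass. ([scan_loci()] uses the
#' fully grid-consistent variant in which the observed per-branch
#' contributions are discretised exactly as the null's were.)
#'
#' @param score Observed binding locus score.
#' @param null A `null_score_dist` from [null_distribution()].
#' @return p-value in (0, 1].
#' @export
locus_significance <- function(score, null) {
  stopifnot(inherits(null, "null_score_dist"))
  if (is.na(score)) return(NA_real_)
  if (score <= 0) return(1)
  upper <- seq_along(null$mass) * null$bin_width # bin upper edges
  p <- sum(null$mass[upper >= score - 1e-12])
  if (p <= 0) p <- min(null$mass[null$mass > 0])
  min(p, 1)
}

#' Scan reference windows for binding loci
#'
#' Slides a window along the reference coordinates of each alignment block
#' (default 200 bp with 20 bp offsets), and for every window computes the
#' per-branch divergence, parent/child site counts and conditional p-values,
#' the combined binding locus score, and its significance under the
#' window-specific convolution null (rebuilt from the window's actual branch
#' conditions, with caching over repeated condition multisets). Windows
#' passing the chosen cutoff are flagged significant and overlapping
#' significant windows are merged into maximal runs reporting their best
#' window.
#'
#' @param blocks A `block_set` of alignments over the tree.
#' @param phy The [phylogeny()].
#' @param pwm A calibrated [pwm()]; must match the one the table was
#'   estimated with.
#' @param table The `transition_table` from [estimate_table()].
#' @param window_size,step Sliding-window geometry on reference coordinates.
#' @param alpha Null p-value cutoff for significance (default 0.05); ignored
#'   when `score_threshold` is given.
#' @param score_threshold Optional raw score cutoff used instead of `alpha`.
#' @param bin_width Null score bin width; see [null_distribution()].
#' @param literal Branch p-value orientation; see [branch_pvalue()].
#' @param bg Background base distribution.
#' @return A `binding_loci` object: tibble of windows (`window_id`,
#'   `block_id`, `chrom`, `start`, `end`, `n_branches`, `score`,
#'   `null_pvalue`, `significant`)
#'   with attributes `sites` (member TFBS of significant windows, reference
#'   coordinates), `merged` (maximal runs of significant windows) and
#'   `params`.
#' @export
scan_loci <- function(blocks, phy, pwm, table, window_size = 200L, step = 20L,
                      alpha = 0.05, score_threshold = NULL, bin_width = 0.05,
                      literal = FALSE, bg = background()) {
  stopifnot(inherits(table, "transition_table"), inherits(pwm, "pwm"))
  windows <- extract_windows(blocks, phy, window_size = window_size, step = step)
  lm <- llr_matrix(pwm, bg)
  lm_rc <- revcomp_lm(lm)
  null_cache <- new.env(parent = emptyenv())
  dist_cache <- new.env(parent = emptyenv())
  res <- vector("list", nrow(windows))
  branch_detail <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    rows <- w$rows[[1L]]
    seqs <- w$seqs[[1L]]
    counts <- vapply(seqs, function(s) {
      count_sites_core(encode_dna(s), lm, lm_rc, pwm$threshold)
    }, numeric(1))
    br <- phy$branches
    br <- br[br$node %in% names(rows) & br$parent %in% names(rows), , drop = FALSE]
    nb <- nrow(br)
    lam <- a <- b <- pv <- rep(NA_real_, nb)
    for (j in seq_len(nb)) {
      l <- divergence(rows[[br$parent[j]]], rows[[br$node[j]]])
      if (is.na(l)) next
      lam[j] <- l
      a[j] <- counts[[br$parent[j]]]
      b[j] <- counts[[br$node[j]]]
      pv[j] <- tryCatch(branch_pvalue(table, l, a[j], b[j], literal = literal),
                        bindingloci_unsupported = function(e) NA_real_)
    }
    ok <- !is.na(pv)
    recs <- tibble::tibble(window_id = w$window_id, node = br$node[ok],
                           lambda = lam[ok], a = a[ok], b = b[ok],
                           pvalue = pv[ok])
    branch_detail[[k]] <- recs
    if (nrow(recs) == 0L) {
      res[[k]] <- tibble::tibble(window_id = w$window_id,
                                 block_id = w$block_id, chrom = w$chrom,
                                 start = w$start, end = w$end,
                                 n_branches = 0L, score = NA_real_,
                                 null_pvalue = NA_real_)
      next
    }
    score <- locus_score(recs$pvalue)
    key <- paste(sort(paste0(recs$lambda, ":", pmin(recs$a, table$a_cap))),
                 collapse = ",")
    null <- null_cache[[key]]
    if (is.null(null)) {
      null <- null_distribution(table, recs[, c("lambda", "a")],
                                bin_width = bin_width, literal = literal,
                                .dist_cache = dist_cache)
      null_cache[[key]] <- null
    }
    res[[k]] <- tibble::tibble(window_id = w$window_id,
                               block_id = w$block_id, chrom = w$chrom,
                               start = w$start, end = w$end,
                               n_branches = nrow(recs), score = score,
                               null_pvalue = locus_significance_binned(recs$pvalue, null))
  }
  loci <- dplyr::bind_rows(res)
  loci$significant <- if (is.null(score_threshold)) {
    !is.na(loci$null_pvalue) & loci$null_pvalue <= alpha
  } else {
    !is.na(loci$score) & loci$score >= score_threshold
  }
  # Member TFBS: reference-sequence hits within significant windows, lifted
  # to reference coordinates.
  sig <- loci[loci$significant, , drop = FALSE]
  sites <- lapply(match(sig$window_id, windows$window_id), function(k) {
    w <- windows[k, ]
    hits <- scan_pwm(w$seqs[[1L]][[phy$reference]], pwm, bg = bg)
    if (nrow(hits) == 0L) return(NULL)
    tibble::tibble(chrom = w$chrom, start = w$start + hits$start,
                   end = w$start + hits$start + pwm$width,
                   name = pwm$id, score = hits$llr, strand = hits$strand,
                   window_id = w$window_id)
  })
  sites <- dplyr::bind_rows(sites)
  if (nrow(sites) > 0L) {
    sites <- dplyr::distinct(sites, .data$chrom, .data$start, .data$end,
                             .data$strand, .keep_all = TRUE)
  }
  structure(
    loci,
    class = c("binding_loci", class(loci)),
    sites = sites,
    branch_detail = dplyr::bind_rows(branch_detail),
    merged = merge_significant(loci),
    params = list(pwm_id = pwm$id, window_size = window_size, step = step,
                  alpha = alpha, score_threshold = score_threshold,
                  bin_width = bin_width, literal = literal)
  )
}

# Merge overlapping/adjacent significant windows into maximal runs; each run
# reports its best window's score and smallest null p-value.
merge_significant <- function(loci) {
  sig <- loci[loci$significant & !is.na(loci$score), , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), score = numeric(),
                          null_pvalue = numeric(), n_windows = integer()))
  }
  sig <- dplyr::arrange(sig, .data$chrom, .data$start)
  run <- cumsum(c(TRUE, sig$chrom[-1L] != sig$chrom[-nrow(sig)] |
                    sig$start[-1L] > cummax_end(sig)[-nrow(sig)]))
  sig$run <- run
  dplyr::summarise(
    dplyr::group_by(sig, .data$run),
    chrom = .data$chrom[1L], start = min(.data$start), end = max(.data$end),
    score = max(.data$score), null_pvalue = min(.data$null_pvalue),
    n_windows = dplyr::n(), .groups = "drop"
  )[, -1L]
}

cummax_end <- function(sig) {
  stats::ave(sig$end, sig$chrom, FUN = cummax)
}

#' @export
print.binding_loci <- function(x, ...) {
  cat(sprintf("<binding_loci> %d windows scanned, %d significant, %d merged runs (pwm %s)\n",
              nrow(x), sum(x$significant, na.rm = TRUE),
              nrow(attr(x, "merged")), attr(x, "params")$pwm_id))
  NextMethod()
}

#' Member TFBS predictions of significant loci
#'
#' @param loci A `binding_loci` object from [scan_loci()].
#' @return Tibble of reference-coordinate sites (BED6-like plus `window_id`).
#' @export
locus_sites <- function(loci) attr(loci, "sites")

#' Merged runs of overlapping significant windows
#'
#' @inheritParams locus_sites
#' @return Tibble: `chrom`, `start`, `end`, best `score`, smallest
#'   `null_pvalue`, `n_windows`.
#' @export
locus_runs <- function(loci) attr(loci, "merged")

#' Per-branch detail of a locus scan
#'
#' @inheritParams locus_sites
#' @return Tibble: `window_id`, `node`, `lambda`, `a`, `b`, `pvalue`.
#' @export
locus_branches <- function(loci) attr(loci, "branch_detail")

#' Tidy method for binding locus scans
#'
#' @param x A `binding_loci` object.
#' @param ... Unused.
#' @return The per-window tibble, without attributes.
#' @export
tidy.binding_loci <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.binding_loci
#' @export
glance.binding_loci <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(pwm_id = p$pwm_id, n_windows = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 n_merged = nrow(attr(x, "merged")),
                 window_size = p$window_size, step = p$step)
}

#' Write loci and member sites as BED
#'
#' Windows (or merged runs) go to `<stem>.loci.bed` as BED6+2 with the locus
#' score scaled into the BED score column and `null_pvalue`, `n_branches`
#' appended; member TFBS go to `<stem>.sites.bed` as BED6 with the LLR as
#' score.
#'
#' @param loci A `binding_loci` object.
#' @param stem Output path stem.
#' @param merged Write merged runs instead of individual windows.
#' @return Character vector of the two paths, invisibly.
#' @export
write_loci_bed <- function(loci, stem, merged = FALSE) {
  p <- attr(loci, "params")
  if (merged) {
    df <- locus_runs(loci)
    df$n_branches <- NA_integer_
  } else {
    df <- tibble::as_tibble(loci)[loci$significant, , drop = FALSE]
  }
  out1 <- paste0(stem, ".loci.bed")
  bed <- tibble::tibble(chrom = df$chrom, start = df$start, end = df$end,
                        name = p$pwm_id,
                        score = round(pmin(1000, df$score * 100)),
                        strand = ".",
                        null_pvalue = signif(df$null_pvalue, 6),
                        n_branches = df$n_branches)
  write_bed(bed, out1)
  out2 <- paste0(stem, ".sites.bed")
  write_bed(locus_sites(loci), out2)
  invisible(c(out1, out2))
}
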