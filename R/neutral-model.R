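# Empirical neutral model of TFBS-count evolution. For every window and
# every tree branch (parent p(u), child u) we record the triple
# (lambda, a, b): integer-percent sequence divergence, parent site count,
# child site count. Normalising counts within each (lambda, a) cell gives
# the transition probabilities Pr[b | a, lambda] under neutral drift, from
# which one-sided conditional p-values of count preservation follow.

#' Estimate the neutral TFBS-count transition table
#'
#' Scans every tree node's gapless sequence in every (non-overlapping)
#' window with a calibrated PWM, records `(lambda, a, b)` for every branch
#' with both sequences present and a defined divergence, and turns the
#' counts into conditional probabilities `Pr[b | a, lambda]`.
#'
#' Sparsity handling: integer-percent divergence cells with fewer than
#' `min_obs` observations for a given parent count `a` are pooled with the
#' nearest neighbouring divergence cell until the minimum is met; counts at
#' or above `a_cap` are collapsed into the cap bin. Within each populated
#' cell, probabilities are additively smoothed over the support
#' `[0, max(b) + 2]`: each child count receives `smooth` pseudo-observations
#' (default 0.5, the Krichevsky-Trofimov choice), so an outcome unobserved
#' among n cell observations is estimated near `0.5 / n` rather than zero --
#' tails are never exactly zero, and never understated by more than the
#' smoothing itself.
#'
#' @param windows Window tibble from [extract_windows()] (estimation mode:
#'   non-overlapping windows).
#' @param phy The [phylogeny()] the window rows are keyed by.
#' @param pwm A calibrated [pwm()].
#' @param min_obs Minimum observations per (pooled lambda, a) cell.
#' @param a_cap Counts above this are pooled into the cap bin.
#' @param smooth Additive pseudocount per child-count outcome within the
#'   cell's support; 0 disables smoothing.
#' @param bg Background distribution for the LLR.
#' @return A `transition_table` object; see [transition_prob()],
#'   [branch_pvalue()], [tidy.transition_table()].
#' @export
estimate_table <- function(windows, phy, pwm, min_obs = 50L, a_cap = 20L,
                           smooth = 0.5, bg = background()) {
  stopifnot(inherits(phy, "phylogeny"), inherits(pwm, "pwm"))
  if (is.na(pwm$threshold)) stop("PWM must be calibrated before estimation")
  obs <- observe_branches(windows, phy, pwm, bg = bg)
  if (nrow(obs) == 0L) {
    stop("no usable (window, branch) observations: all branches missing ",
         "data or undefined divergence")
  }
  capped <- sum(obs$a >= a_cap | obs$b >= a_cap)
  if (capped > 0L) {
    message(capped, " observations with counts >= ", a_cap,
            " pooled into the cap bin")
  }
  obs$a <- pmin(obs$a, a_cap)
  obs$b <- pmin(obs$b, a_cap)
  cells <- pool_and_normalise(obs, min_obs, smooth)
  structure(
    list(pwm_id = pwm$id, threshold = pwm$threshold,
         window_size = nchar(windows$seqs[[1L]][[phy$reference]]),
         min_obs = as.integer(min_obs), a_cap = as.integer(a_cap),
         smooth = smooth, cells = cells, n_obs = nrow(obs)),
    class = "transition_table"
  )
}

# One row per usable (window, branch): lambda, a, b.
observe_branches <- function(windows, phy, pwm, bg = background()) {
  lm <- llr_matrix(pwm, bg)
  lm_rc <- revcomp_lm(lm)
  res <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    rows <- windows$rows[[k]]
    seqs <- windows$seqs[[k]]
    counts <- vapply(seqs, function(s) {
      count_sites_core(encode_dna(s), lm, lm_rc, pwm$threshold)
    }, numeric(1))
    br <- phy$branches
    have <- br$node %in% names(rows) & br$parent %in% names(rows)
    if (!any(have)) next
    br <- br[have, , drop = FALSE]
    lam <- vapply(seq_len(nrow(br)), function(j) {
      divergence(rows[[br$parent[j]]], rows[[br$node[j]]])
    }, integer(1))
    keep <- !is.na(lam)
    if (!any(keep)) next
    res[[k]] <- tibble::tibble(
      window_id = windows$window_id[k],
      node = br$node[keep],
      lambda = lam[keep],
      a = unname(counts[br$parent[keep]]),
      b = unname(counts[br$node[keep]])
    )
  }
  dplyr::bind_rows(res)
}

# Greedy nearest-neighbour pooling of lambda bins per parent count a, then
# per-cell normalisation with additive smoothing. Returns a tibble with one
# row per (a, pool): lambda_min, lambda_max, n_obs, and list columns b /
# count / prob over the cell's support.
pool_and_normalise <- function(obs, min_obs, smooth) {
  out <- list()
  for (a_val in sort(unique(obs$a))) {
    sub <- obs[obs$a == a_val, , drop = FALSE]
    lam_tab <- dplyr::count(sub, .data$lambda)
    lam_tab <- lam_tab[order(lam_tab$lambda), , drop = FALSE]
    # walk lambda bins in order, closing a pool once min_obs is reached
    pool <- integer(nrow(lam_tab))
    acc <- 0L; pid <- 1L
    for (j in seq_len(nrow(lam_tab))) {
      pool[j] <- pid
      acc <- acc + lam_tab$n[j]
      if (acc >= min_obs) { pid <- pid + 1L; acc <- 0L }
    }
    if (acc > 0L && pid > 1L) pool[pool == pid] <- pid - 1L # fold short tail
    lam_tab$pool <- pool
    sub$pool <- lam_tab$pool[match(sub$lambda, lam_tab$lambda)]
    for (p in unique(lam_tab$pool)) {
      cell <- sub[sub$pool == p, , drop = FALSE]
      support_max <- max(cell$b) + 2L
      bs <- 0:support_max
      cnt <- tabulate(cell$b + 1L, nbins = support_max + 1L)
      prob <- (cnt + smooth) / (sum(cnt) + smooth * length(cnt))
      out[[length(out) + 1L]] <- tibble::tibble(
        a = a_val,
        lambda_min = min(cell$lambda), lambda_max = max(cell$lambda),
        n_obs = nrow(cell),
        b = list(bs), count = list(cnt), prob = list(prob)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Build a transition table from explicit cell probabilities
#'
#' Mainly for controlled experiments and toy examples: supply the
#' per-(divergence, parent count) child-count distributions directly instead
#' of estimating them from alignments.
#'
#' @param cells Data frame with columns `a`, `lambda_min`, `lambda_max` and
#'   a list column `prob` whose j-th element of each vector is the
#'   probability of child count `b = j - 1`; optionally `n_obs`.
#' @param a_cap,smooth,min_obs,window_size,pwm_id,threshold Metadata;
#'   see [estimate_table()].
#' @return A `transition_table` object.
#' @export
#' @examples
#' toy <- transition_table(tibble::tibble(
#'   a = 2, lambda_min = 10, lambda_max = 10,
#'   prob = list(c(0.5, 0.3, 0.15, 0.05))))
#' branch_pvalue(toy, 10, 2, 2) # 0.20
transition_table <- function(cells, a_cap = 20L, smooth = 0,
                             min_obs = 1L, window_size = 200L,
                             pwm_id = "manual", threshold = NA_real_) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("a", "lambda_min", "lambda_max", "prob") %in% names(cells)))
  if (!all(vapply(cells$prob, function(p) abs(sum(p) - 1) < 1e-9, logical(1)))) {
    stop("each cell's probabilities must sum to 1")
  }
  if (!"n_obs" %in% names(cells)) cells$n_obs <- NA_integer_
  cells$b <- lapply(cells$prob, function(p) seq_along(p) - 1L)
  if (!"count" %in% names(cells)) {
    cells$count <- lapply(cells$prob, function(p) rep(NA_integer_, length(p)))
  }
  cells <- cells[, c("a", "lambda_min", "lambda_max", "n_obs", "b", "count", "prob")]
  structure(
    list(pwm_id = pwm_id, threshold = threshold, window_size = window_size,
         min_obs = as.integer(min_obs), a_cap = as.integer(a_cap),
         smooth = smooth, cells = cells,
         n_obs = sum(cells$n_obs, na.rm = TRUE)),
    class = "transition_table"
  )
}

# Locate the (pooled) cell for (lambda, a); NULL if a itself is unsupported.
find_cell <- function(table, lambda, a) {
  a <- min(a, table$a_cap)
  cells <- table$cells[table$cells$a == a, , drop = FALSE]
  if (nrow(cells) == 0L) return(NULL)
  inside <- lambda >= cells$lambda_min & lambda <= cells$lambda_max
  if (any(inside)) return(cells[which(inside)[1L], , drop = FALSE])
  d <- pmax(cells$lambda_min - lambda, lambda - cells$lambda_max)
  cells[which.min(d), , drop = FALSE]
}

unsupported_condition <- function(lambda, a) {
  structure(
    class = c("bindingloci_unsupported", "error", "condition"),
    list(message = sprintf("unsupported condition: no cell for (lambda=%s, a=%s)",
                           lambda, a),
         call = sys.call(-1L))
  )
}

#' Neutral transition probability Pr[b | a, lambda]
#'
#' Looks up the pooled, smoothed cell for the given divergence and parent
#' count. Divergences outside any pooled range for that `a` use the nearest
#' pool; a parent count never observed (even after capping) raises an
#' `"bindingloci_unsupported"` condition, which callers catch to skip the
#' branch.
#'
#' @param table A `transition_table` from [estimate_table()].
#' @param lambda Integer-percent divergence.
#' @param a Parent (ancestral) site count.
#' @param b Child site count.
#' @return Probability; 0 if `b` is beyond the cell's smoothed support.
#' @export
transition_prob <- function(table, lambda, a, b) {
  cell <- find_cell(table, lambda, a)
  if (is.null(cell)) stop(unsupported_condition(lambda, a))
  b <- min(b, table$a_cap)
  pr <- cell$prob[[1L]]
  if (b > length(pr) - 1L) return(0)
  pr[b + 1L]
}

#' One-sided branch p-value of TFBS-count preservation
#'
#' The probability that, under neutral drift at the observed divergence and
#' conditioned on the parent count `a`, the count change `b' - a` is at
#' least as large as the observed change `b - a`; equivalently the tail
#' `sum over b' >= b of Pr[b' | a, lambda]`. Small values mean the window
#' preserved (or gained) predicted sites to a degree neutral sequences
#' rarely match. A total loss (`b = 0`) always gives p = 1.
#'
#' With `literal = TRUE` the tail is instead taken over `b' >= 2a - b`,
#' i.e. the observed change is measured parent-minus-child; this variant
#' treats losses as surprising and is provided for comparison only.
#'
#' @inheritParams transition_prob
#' @param literal Use the parent-minus-child orientation for the observed
#'   change (not recommended; see Details).
#' @return p-value in (0, 1]; zero-mass tails are floored at the cell's
#'   smallest positive probability.
#' @export
branch_pvalue <- function(table, lambda, a, b, literal = FALSE) {
  cell <- find_cell(table, lambda, a)
  if (is.null(cell)) stop(unsupported_condition(lambda, a))
  b <- min(b, table$a_cap)
  a_capped <- min(a, table$a_cap)
  cut <- if (literal) 2L * a_capped - b else b
  pr <- cell$prob[[1L]]
  support <- seq_along(pr) - 1L
  p <- sum(pr[support >= cut])
  if (p <= 0) p <- min(pr[pr > 0])
  min(p, 1)
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf(
    "<transition_table> pwm=%s  window=%dbp  %d observations, %d cells (a <= %d)\n",
    x$pwm_id, x$window_size, x$n_obs, nrow(x$cells), x$a_cap))
  invisible(x)
}

#' Tidy a transition table into one row per (cell, child count)
#'
#' @param x A `transition_table`.
#' @param ... Unused.
#' @return Tibble: `a`, `lambda_min`, `lambda_max`, `n_obs`, `b`, `count`,
#'   `prob`.
#' @export
tidy.transition_table <- function(x, ...) {
  tidyr::unnest(x$cells, cols = c("b", "count", "prob"))
}

#' One-line summary of a transition table
#'
#' @inheritParams tidy.transition_table
#' @return Tibble with the table's metadata and size.
#' @export
glance.transition_table <- function(x, ...) {
  tibble::tibble(pwm_id = x$pwm_id, window_size = x$window_size,
                 n_obs = x$n_obs, n_cells = nrow(x$cells),
                 a_cap = x$a_cap, min_obs = x$min_obs,
                 smooth = x$smooth)
}

#' Write / read a transition table as tab-separated text
#'
#' The file carries the table metadata in `#key=value` header lines followed
#' by one row per (cell, b): `pwm_id`, `a`, `lambda_min`, `lambda_max`,
#' `n_obs`, `b`, `count`, `prob`. Reading reconstructs an object whose
#' scoring behaviour is identical to the original.
#'
#' @param table A `transition_table`.
#' @param path File path.
#' @return `write_transition_table()` returns `path` invisibly;
#'   `read_transition_table()` returns the reconstructed object.
#' @export
write_transition_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(pwm_id = table$pwm_id, threshold = format(table$threshold, digits = 17),
            window_size = table$window_size, min_obs = table$min_obs,
            a_cap = table$a_cap, smooth = format(table$smooth, digits = 17),
            n_obs = table$n_obs)
  writeLines(paste0("#", names(meta), "=", meta), con)
  flat <- tidy.transition_table(table)
  flat$pwm_id <- table$pwm_id
  flat$prob <- format(flat$prob, digits = 17)
  flat <- flat[, c("pwm_id", "a", "lambda_min", "lambda_max",
                   "n_obs", "b", "count", "prob")]
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_table
#' @export
read_transition_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                          vapply(kv, `[[`, character(1), 1L))
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  cells <- body |>
    dplyr::group_by(.data$a, .data$lambda_min, .data$lambda_max, .data$n_obs) |>
    dplyr::summarise(b = list(.data$b), count = list(.data$count),
                     prob = list(.data$prob), .groups = "drop") |>
    dplyr::arrange(.data$a, .data$lambda_min)
  structure(
    list(pwm_id = unname(meta["pwm_id"]),
         threshold = as.numeric(meta["threshold"]),
         window_size = as.integer(meta["window_size"]),
         min_obs = as.integer(meta["min_obs"]),
         a_cap = as.integer(meta["a_cap"]),
         smooth = as.numeric(meta["smooth"]),
         cells = tibble::as_tibble(cells),
         n_obs = as.integer(meta["n_obs"])),
    class = "transition_table"
  )
}
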