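# Evaluation protocol: three ranked prediction methods scored by positive
# predictive value against bound-region intervals (e.g. ChIP-Seq peaks).
# All intervals are 0-based half-open on reference coordinates.

merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- dplyr::arrange(df[, c("chrom", "start", "end")], .data$chrom, .data$start)
  df$run <- cumsum(c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)] |
                       df$start[-1L] > stats::ave(df$end, df$chrom, FUN = cummax)[-nrow(df)]))
  dplyr::summarise(dplyr::group_by(df, .data$run),
                   chrom = .data$chrom[1L], start = min(.data$start),
                   end = max(.data$end), .groups = "drop")[, -1L]
}

overlaps_any <- function(df, peaks) {
  if (nrow(peaks) == 0L) return(rep(FALSE, nrow(df)))
  vapply(seq_len(nrow(df)), function(i) {
    any(peaks$chrom == df$chrom[i] &
          peaks$start < df$end[i] & peaks$end > df$start[i])
  }, logical(1))
}

# Number of bases of [start, end) covered by the (merged) peaks.
bases_covered <- function(df, peaks) {
  vapply(seq_len(nrow(df)), function(i) {
    p <- peaks[peaks$chrom == df$chrom[i] &
                 peaks$start < df$end[i] & peaks$end > df$start[i], , drop = FALSE]
    if (nrow(p) == 0L) return(0)
    sum(pmin(p$end, df$end[i]) - pmax(p$start, df$start[i]))
  }, numeric(1))
}

new_ranked <- function(df, method) {
  stopifnot(all(diff(df$score) <= 1e-12 | is.na(diff(df$score))))
  structure(df, class = c("ranked_predictions", class(df)), method = method)
}

#' Rank single-genome PWM hits by LLR
#'
#' The baseline predictor: every site on either strand whose LLR strictly
#' exceeds the PWM's calibrated threshold, best score first. Lowering a
#' score cutoff along this ranking reproduces the predictions obtained by
#' varying the LLR threshold above the calibrated minimum.
#'
#' @param seqs Named character vector of reference sequences (names =
#'   chromosome), or a single string (chromosome `"chr"`).
#' @param pwm Calibrated [pwm()].
#' @param bg Background base distribution.
#' @return A `ranked_predictions` tibble: `chrom`, `start`, `end`, `strand`,
#'   `score` (LLR), non-increasing in `score`.
#' @export
rank_pwm_scan <- function(seqs, pwm, bg = background()) {
  if (is.null(names(seqs))) names(seqs) <- rep("chr", length(seqs))
  hits <- dplyr::bind_rows(lapply(names(seqs), function(ch) {
    h <- scan_pwm(seqs[[ch]], pwm, bg = bg)
    if (nrow(h) == 0L) return(NULL)
    tibble::tibble(chrom = ch, start = h$start, end = h$start + pwm$width,
                   strand = h$strand, score = h$llr)
  }))
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           score = numeric())
  }
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$chrom,
                         .data$start, .data$strand)
  new_ranked(hits, "pwm_scan")
}

#' Rank PWM hits restricted to conserved regions
#'
#' The phylogenetic-footprinting baseline: the [rank_pwm_scan()] predictions
#' filtered to those overlapping a conserved-region interval (e.g. a
#' PhastCons element) by at least one base.
#'
#' @inheritParams rank_pwm_scan
#' @param conserved Tibble of conserved intervals (`chrom`, `start`, `end`),
#'   e.g. from [read_bed()].
#' @return A `ranked_predictions` tibble, as [rank_pwm_scan()].
#' @export
rank_conserved_scan <- function(seqs, pwm, conserved, bg = background()) {
  base <- rank_pwm_scan(seqs, pwm, bg = bg)
  keep <- overlaps_any(base, merge_intervals(conserved))
  new_ranked(tibble::as_tibble(base)[keep, , drop = FALSE], "conserved_scan")
}

#' Rank member TFBS of binding loci by locus score
#'
#' The ancestral-genome-aware predictor's ranking: member sites of scored
#' windows ordered by their window's binding locus score (descending), ties
#' broken by site LLR (descending) then coordinate. Lowering a locus-score
#' cutoff along this ranking reproduces the predictions obtained by varying
#' the binding-locus-score threshold while keeping the LLR threshold at the
#' calibrated minimum.
#'
#' @param loci A `binding_loci` object from [scan_loci()]; sites of all
#'   windows flagged significant there are ranked (run the scan with a
#'   permissive cutoff to rank more sites).
#' @return A `ranked_predictions` tibble: `chrom`, `start`, `end`, `strand`,
#'   `score` (the locus score), `llr`, `window_id`.
#' @export
rank_binding_loci <- function(loci) {
  sites <- locus_sites(loci)
  if (is.null(sites) || nrow(sites) == 0L) {
    return(new_ranked(tibble::tibble(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     score = numeric(), llr = numeric()),
                      "binding_loci"))
  }
  win <- tibble::as_tibble(loci)[, c("window_id", "score")]
  df <- dplyr::inner_join(sites, win, by = "window_id",
                          suffix = c("_llr", ""))
  df <- tibble::tibble(chrom = df$chrom, start = df$start, end = df$end,
                       strand = df$strand, score = df$score,
                       llr = df$score_llr, window_id = df$window_id)
  # A site inside several overlapping significant windows is ranked once,
  # by its best window.
  df <- dplyr::arrange(df, dplyr::desc(.data$score), dplyr::desc(.data$llr),
                       .data$chrom, .data$start, .data$strand)
  df <- dplyr::distinct(df, .data$chrom, .data$start, .data$end, .data$strand,
                        .keep_all = TRUE)
  new_ranked(df, "binding_loci")
}

#' Positive-predictive-value curve of a ranked prediction set
#'
#' For each prefix of the ranking, the fraction of predictions overlapping a
#' (merged) bound region by at least one base (`ppv_site`), and the fraction
#' of predicted bases lying inside bound regions (`ppv_base`).
#'
#' @param preds A `ranked_predictions` tibble.
#' @param peaks Tibble of bound-region intervals (`chrom`, `start`, `end`);
#'   overlapping peaks are merged before testing.
#' @param n_points Number of prefix sizes to report (evenly spaced up to the
#'   number of predictions); `NULL` reports every prefix.
#' @return Tibble: `method`, `n`, `ppv_site`, `ppv_base`.
#' @export
ppv_curve <- function(preds, peaks, n_points = NULL) {
  stopifnot(nrow(preds) >= 1L)
  method <- attr(preds, "method") %||% "predictions"
  pk <- merge_intervals(peaks)
  hit <- overlaps_any(preds, pk)
  cov <- bases_covered(preds, pk)
  len <- preds$end - preds$start
  ns <- if (is.null(n_points)) seq_len(nrow(preds)) else {
    unique(pmax(1L, round(seq_len(n_points) * nrow(preds) / n_points)))
  }
  tibble::tibble(
    method = method, n = as.integer(ns),
    ppv_site = cumsum(hit)[ns] / ns,
    ppv_base = cumsum(cov)[ns] / cumsum(len)[ns]
  )
}

#' Plot PPV curves
#'
#' @param curves One tibble from [ppv_curve()] or several row-bound together.
#' @param base_level Plot base-level instead of site-level PPV.
#' @return A ggplot object.
#' @export
plot_ppv <- function(curves, base_level = FALSE) {
  y <- if (base_level) "ppv_base" else "ppv_site"
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$n, y = .data[[y]],
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of TFBS predicted",
                  y = if (base_level) "PPV (bases)" else "PPV (sites)",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
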