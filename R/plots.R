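#' Retention probability of a site count under neutral drift
#'
#' For each pooled divergence cell at parent count `a`, the probability that
#' a neutrally evolving window still holds at least `b_min` predicted sites,
#' `Pr[b >= b_min | a, lambda]`. This is the drift summary contrasted across
#' transcription factors: information-rich motifs lose sites faster and
#' settle at a lower stationary retention than degenerate ones.
#'
#' @param table A `transition_table`.
#' @param a Parent site count to condition on (default 2).
#' @param b_min Retention cutoff; defaults to `a` (count fully preserved or
#'   grown).
#' @return Tibble: `lambda_min`, `lambda_max`, `lambda_mid`, `n_obs`,
#'   `retention`.
#' @export
retention_prob <- function(table, a = 2L, b_min = a) {
  cells <- table$cells[table$cells$a == min(a, table$a_cap), , drop = FALSE]
  if (nrow(cells) == 0L) {
    stop(unsupported_condition(NA, a))
  }
  tibble::tibble(
    lambda_min = cells$lambda_min, lambda_max = cells$lambda_max,
    lambda_mid = (cells$lambda_min + cells$lambda_max) / 2,
    n_obs = cells$n_obs,
    retention = vapply(cells$prob, function(pr) {
      sum(pr[seq_along(pr) - 1L >= b_min])
    }, numeric(1))
  )
}

#' Plot neutral drift of TFBS counts
#'
#' Draws the distribution of the descendant site count against divergence
#' for windows whose parent holds `a` predicted sites: one line per child
#' count `b`, probabilities from the table's pooled cells.
#'
#' @param object A `transition_table`.
#' @param a Parent count to condition on.
#' @param max_b Largest child count drawn individually.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_table <- function(object, a = 2L, max_b = 4L, ...) {
  flat <- tidy(object)
  flat <- flat[flat$a == min(a, object$a_cap) & flat$b <= max_b, , drop = FALSE]
  flat$lambda_mid <- (flat$lambda_min + flat$lambda_max) / 2
  ggplot2::ggplot(flat, ggplot2::aes(x = .data$lambda_mid, y = .data$prob,
                                     colour = factor(.data$b))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "divergence (%)",
                  y = sprintf("Pr[b | a = %d, lambda]", a),
                  colour = "descendant\ncount b") +
    ggplot2::theme_minimal()
}

#' Plot a binding-locus scan along the reference
#'
#' Window scores along reference coordinates, significant windows
#' highlighted and merged runs underlined.
#'
#' @param object A `binding_loci` object from [scan_loci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_loci <- function(object, ...) {
  df <- tibble::as_tibble(object)
  runs <- locus_runs(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                         y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 na.value = "grey85") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "reference position (bp)", y = "binding locus score",
                  colour = "significant") +
    ggplot2::theme_minimal()
  if (nrow(runs) > 0L) {
    gg <- gg + ggplot2::geom_segment(
      data = runs,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
      inherit.aes = FALSE, linewidth = 1.6, colour = "firebrick")
  }
  gg
}
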