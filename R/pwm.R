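#' Construct a position weight matrix (PWM)
#'
#' A PWM models the base preference of a transcription factor as one
#' probability distribution over A/C/G/T per position. Matrices may be given
#' as counts or as probabilities; a pseudocount is added to every cell before
#' column normalisation so that no cell is exactly zero (a zero cell would
#' give a log-likelihood ratio of minus infinity).
#'
#' @param mat Numeric matrix, 4 rows (A, C, G, T) by `w >= 4` columns, of
#'   counts or probabilities. A `w x 4` matrix is transposed on input when
#'   its row names or dimensions identify the orientation.
#' @param id Identifier (accession and/or factor name).
#' @param pseudocount Mass added to every cell before normalisation
#'   (default 0.01).
#' @param threshold Optional calibrated LLR threshold (natural-log units);
#'   usually set later by [calibrate_threshold()].
#' @return An object of class `pwm`: a list with elements `id`, `mat`
#'   (4 x w column-stochastic matrix), `width`, `pseudocount`, `threshold`.
#' @seealso [read_transfac()], [read_jaspar()], [calibrate_threshold()],
#'   [scan_pwm()]
#' @export
#' @examples
#' m <- matrix(c(10, 0, 0, 0, 0, 10, 0, 0, 0, 0, 10, 0, 0, 0, 0, 10), nrow = 4)
#' pwm(m, id = "toy", pseudocount = 0)
pwm <- function(mat, id = "pwm", pseudocount = 0.01, threshold = NA_real_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L && ncol(mat) == 4L) mat <- t(mat)
  if (nrow(mat) != 4L) {
    stop("PWM matrix must have 4 rows (A, C, G, T); got ", nrow(mat), " for '", id, "'")
  }
  if (ncol(mat) < 4L) {
    stop("PWM '", id, "' has width ", ncol(mat), "; need >= 4")
  }
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("PWM '", id, "' contains negative or non-finite entries")
  }
  mat <- mat + pseudocount
  csum <- colSums(mat)
  if (any(csum <= 0)) {
    stop("PWM '", id, "' has an all-zero column and zero pseudocount")
  }
  mat <- sweep(mat, 2L, csum, "/")
  rownames(mat) <- DNA_BASES
  colnames(mat) <- NULL
  structure(
    list(id = id, mat = mat, width = ncol(mat),
         pseudocount = pseudocount, threshold = threshold),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  width=%d  pseudocount=%g  threshold=%s\n",
              x$id, x$width, x$pseudocount,
              if (is.na(x$threshold)) "uncalibrated" else format(x$threshold, digits = 4)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Uniform (or custom) background base distribution
#'
#' The denominator of the log-likelihood ratio. Defaults to uniform; the
#' vector must be strictly positive and is renormalised to sum to one.
#'
#' @param p Numeric length-4 vector of A/C/G/T probabilities.
#' @return Named numeric vector summing to 1.
#' @export
background <- function(p = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(length(p) == 4L, all(is.finite(p)), all(p > 0))
  p <- p / sum(p)
  names(p) <- DNA_BASES
  p
}

#' Information content of a PWM
#'
#' Total relative entropy of the matrix against the background,
#' `sum_j sum_b p_jb * log2(p_jb / q_b)`, in bits. Under a uniform background
#' this is at most 2 bits per position.
#'
#' @inheritParams scan_pwm
#' @param bg Background base distribution, see [background()].
#' @return Information content in bits.
#' @export
#' @examples
#' cons <- pwm(diag(4)[, c(1, 2, 3, 4)] * 10, pseudocount = 0)
#' information_content(cons) # 8 bits: 2 per deterministic position
information_content <- function(pwm, bg = background()) {
  stopifnot(inherits(pwm, "pwm"))
  p <- pwm$mat
  term <- p * log2(p / bg)
  sum(term[p > 0]) # 0 * log(0) contributes nothing
}

# Per-position natural-log LLR lookup matrix (4 x w).
llr_matrix <- function(pwm, bg = background()) {
  log(pwm$mat / bg)
}

#' Log-likelihood-ratio score of one sequence window
#'
#' Scores a sequence of exactly the PWM's width:
#' `sum_i ln(pwm[base_i, i] / bg[base_i])`, in natural-log units.
#'
#' @param seq DNA string of length equal to the PWM width, A/C/G/T only.
#' @inheritParams information_content
#' @return The LLR score (natural log).
#' @export
llr_score <- function(seq, pwm, bg = background()) {
  stopifnot(inherits(pwm, "pwm"))
  code <- encode_dna(seq)
  if (length(code) != pwm$width) {
    stop("sequence length ", length(code), " != PWM width ", pwm$width)
  }
  if (anyNA(code)) stop("sequence contains non-ACGT characters")
  lm <- llr_matrix(pwm, bg)
  sum(lm[cbind(code, seq_along(code))])
}

# Vectorised per-offset forward-strand scores for an encoded sequence.
# Offsets overlapping an ambiguous base (NA code) score NA.
scores_forward <- function(code, lm) {
  w <- ncol(lm)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  idx <- outer(seq_len(n) - 1L, seq_len(w), "+") # n x w positions
  val <- matrix(lm[cbind(as.vector(code[idx]), rep(seq_len(w), each = n))],
                nrow = n)
  rowSums(val)
}

#' Scan a sequence with a PWM on both strands
#'
#' Every offset is scored on the forward strand and on the reverse-complement
#' interpretation of the same window (minus strand). A site is reported iff
#' its LLR score strictly exceeds the threshold. Overlapping sites, and
#' plus/minus hits at the same offset, are all reported individually. Windows
#' overlapping an ambiguous base (N etc.) are skipped.
#'
#' @param seq Gapless DNA string.
#' @param pwm A [pwm()] object.
#' @param threshold LLR cutoff; defaults to the PWM's calibrated threshold.
#' @param bg Background base distribution.
#' @return A tibble with columns `start` (0-based offset of the window's
#'   leftmost base on the forward strand), `strand` (`"+"`/`"-"`) and `llr`,
#'   ordered by `start` then strand.
#' @export
#' @examples
#' p <- pwm(matrix(c(9, 0, 0, 0,  0, 9, 0, 0,  0, 0, 9, 0,  0, 0, 0, 9), 4))
#' scan_pwm("TTACGTTT", p, threshold = 5)
scan_pwm <- function(seq, pwm, threshold = pwm$threshold, bg = background()) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(threshold) || is.na(threshold)) {
    stop("PWM '", pwm$id, "' has no threshold; calibrate it or pass one")
  }
  code <- encode_dna(seq)
  w <- pwm$width
  empty <- tibble::tibble(start = integer(), strand = character(), llr = numeric())
  if (length(code) < w) return(empty)
  lm <- llr_matrix(pwm, bg)
  fwd <- scores_forward(code, lm)
  # Minus strand: score of revcomp(window) under the PWM equals scanning the
  # forward encoding with the reverse-complemented LLR matrix.
  lm_rc <- lm[4:1, w:1, drop = FALSE]
  rev_ <- scores_forward(code, lm_rc)
  hits_f <- which(!is.na(fwd) & fwd > threshold)
  hits_r <- which(!is.na(rev_) & rev_ > threshold)
  out <- tibble::tibble(
    start = c(hits_f, hits_r) - 1L,
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    llr = c(fwd[hits_f], rev_[hits_r])
  )
  dplyr::arrange(out, .data$start, .data$strand)
}

# Fast internal counting path: no tibble assembly. `lm`/`lm_rc` are the
# forward and reverse-complement LLR lookup matrices.
count_sites_core <- function(code, lm, lm_rc, threshold) {
  f <- scores_forward(code, lm)
  r <- scores_forward(code, lm_rc)
  sum(!is.na(f) & f > threshold) + sum(!is.na(r) & r > threshold)
}

revcomp_lm <- function(lm) lm[4:1, ncol(lm):1, drop = FALSE]

#' Count predicted binding sites in a sequence
#'
#' The number of sites whose LLR strictly exceeds the PWM's calibrated
#' threshold, counting overlapping and opposite-strand hits individually.
#' This count is the statistic whose evolution the neutral model describes.
#'
#' @inheritParams scan_pwm
#' @return Integer count.
#' @export
count_sites <- function(seq, pwm, threshold = pwm$threshold, bg = background()) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(threshold) || is.na(threshold)) {
    stop("PWM '", pwm$id, "' has no threshold; calibrate it or pass one")
  }
  code <- encode_dna(seq)
  if (length(code) < pwm$width) return(0L)
  lm <- llr_matrix(pwm, bg)
  as.integer(count_sites_core(code, lm, revcomp_lm(lm), threshold))
}

#' Calibrate a PWM's LLR threshold by sampling
#'
#' Draws `n_samples` sequences position-independently from the PWM's own
#' column distributions, scores each with the LLR, and returns the
#' `percentile`-th percentile score under the nearest-rank definition (the
#' `ceiling(n * p / 100)`-th smallest). With the default 1000 samples and
#' 10th percentile, 900 of the sampled sequences score strictly above the
#' returned threshold whenever scores are tie-free, so most genuine sites
#' pass the cutoff.
#'
#' @inheritParams information_content
#' @param n_samples Number of sequences to draw (>= 10).
#' @param percentile Percentile (0-100) of the sampled score distribution.
#' @param seed Integer seed; sampling is deterministic given it.
#' @return The PWM with its `threshold` field set.
#' @export
calibrate_threshold <- function(pwm, n_samples = 1000L, percentile = 10,
                                seed = 1L, bg = background()) {
  stopifnot(inherits(pwm, "pwm"), n_samples >= 10L,
            percentile > 0, percentile < 100)
  lm <- llr_matrix(pwm, bg)
  w <- pwm$width
  scores <- withr::with_seed(seed, {
    draws <- vapply(seq_len(w), function(j) {
      sample.int(4L, n_samples, replace = TRUE, prob = pwm$mat[, j])
    }, integer(n_samples))
    rowSums(matrix(lm[cbind(as.vector(draws), rep(seq_len(w), each = n_samples))],
                   nrow = n_samples))
  })
  k <- ceiling(n_samples * percentile / 100)
  thr <- sort(scores)[k]
  if (length(unique(scores)) == 1L) {
    warning("all ", n_samples, " calibration samples for '", pwm$id,
            "' score identically (", format(thr, digits = 4),
            "); threshold is tie-degenerate")
  }
  pwm$threshold <- thr
  pwm
}

#' Build a synthetic PWM with a target information content
#'
#' Each column puts probability `c` on a consensus base and `(1 - c) / 3` on
#' the others, with `c` solved numerically so the total information content
#' (uniform background) hits `info_bits`. Useful for controlled simulation
#' studies contrasting information-rich and degenerate motifs.
#'
#' @param width Motif width.
#' @param info_bits Target total information content in bits
#'   (0 < info_bits < 2 * width).
#' @param consensus Optional consensus string of length `width`; the default
#'   is a deterministic non-palindromic pattern (AC repeats closed by G), so
#'   sites do not silently double-count on both strands.
#' @param id Identifier for the new PWM.
#' @return A [pwm()] object (uncalibrated).
#' @export
synthetic_pwm <- function(width, info_bits, consensus = NULL, id = NULL) {
  stopifnot(width >= 4, info_bits > 0, info_bits < 2 * width)
  per_col <- info_bits / width
  ic1 <- function(c) {
    o <- (1 - c) / 3
    c * log2(c / 0.25) + 3 * o * ifelse(o > 0, log2(o / 0.25), 0) - per_col
  }
  cmax <- 1 - 1e-12
  cc <- stats::uniroot(ic1, c(0.25 + 1e-9, cmax), tol = 1e-12)$root
  if (is.null(consensus)) {
    consensus <- paste(c(rep(c("A", "C"), length.out = width - 1L), "G"),
                       collapse = "")
  }
  cons <- encode_dna(consensus)
  stopifnot(length(cons) == width, !anyNA(cons))
  mat <- matrix((1 - cc) / 3, nrow = 4, ncol = width)
  mat[cbind(cons, seq_len(width))] <- cc
  pwm(mat, id = id %||% sprintf("synth_w%d_%.1fbit", width, info_bits),
      pseudocount = 0)
}
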