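#' Tile reference windows over alignment blocks
#'
#' Windows are laid on reference-genome coordinates within each block (they
#' never span block boundaries): starts at `ref_start`, `ref_start + step`,
#' ... as long as a full `window_size` of reference sequence remains. For
#' neutral-model estimation use `step = window_size` (non-overlapping
#' windows); for genome scanning use a small step such as 20 bp. Each window
#' carries, for every tree node with a row in the block, the gapped row over
#' the alignment columns spanned by the reference window and the gapless
#' sequence obtained by deleting gap characters; nodes without a row are
#' recorded in `missing`. Windows overlapping `mask` intervals (e.g. coding
#' exons) are dropped.
#'
#' @param blocks A `block_set` from [read_alignment_fasta()], [read_maf()] or
#'   [simulate_blocks()].
#' @param phy A [phylogeny()]; block row names must be tree node names.
#' @param window_size Window length on the reference, default 200 bp.
#' @param step Offset between successive window starts; defaults to
#'   `window_size` (non-overlapping tiling).
#' @param mask Optional tibble of intervals (`chrom`, `start`, `end`) to
#'   exclude.
#' @return A tibble with one row per window: `window_id`, `block_id`,
#'   `chrom`, `start`, `end`, `rows` (named gapped rows), `seqs` (named
#'   gapless sequences) and `missing` (character vector of absent nodes).
#' @export
extract_windows <- function(blocks, phy, window_size = 200L,
                            step = window_size, mask = NULL) {
  stopifnot(inherits(phy, "phylogeny"), window_size >= 1L, step >= 1L)
  known <- node_names(phy)
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    rows <- blocks$rows[[i]]
    bad <- setdiff(names(rows), known)
    if (length(bad)) {
      stop("block ", blocks$block_id[i],
           ": alignment rows not in the tree: ", paste(bad, collapse = ", "))
    }
    ref <- blocks$ref[i] %||% phy$reference
    if (!ref %in% names(rows)) {
      stop("block ", blocks$block_id[i], ": reference row '", ref, "' absent")
    }
    mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
    rownames(mat) <- names(rows)
    ref_chars <- mat[ref, ]
    ref_cols <- which(!ref_chars %in% c("-", "."))
    nref <- length(ref_cols)
    if (nref != blocks$ref_end[i] - blocks$ref_start[i]) {
      stop("block ", blocks$block_id[i], ": reference gapless length ", nref,
           " does not match header coordinates")
    }
    if (nref < window_size) next
    starts <- seq(0L, nref - window_size, by = step)
    absent <- setdiff(known, names(rows))
    winlist <- lapply(starts, function(s) {
      col_lo <- ref_cols[s + 1L]
      col_hi <- ref_cols[s + window_size]
      sub <- mat[, col_lo:col_hi, drop = FALSE]
      gapped <- apply(sub, 1L, paste, collapse = "")
      tibble::tibble(
        block_id = blocks$block_id[i],
        chrom = blocks$chrom[i],
        start = blocks$ref_start[i] + s,
        end = blocks$ref_start[i] + s + window_size,
        rows = list(gapped),
        seqs = list(vapply(gapped, ungap, character(1))),
        missing = list(absent)
      )
    })
    out[[i]] <- dplyr::bind_rows(winlist)
  }
  win <- dplyr::bind_rows(out)
  if (nrow(win) == 0L) {
    stop("no windows of size ", window_size, " fit in the supplied blocks")
  }
  if (!is.null(mask) && nrow(mask) > 0L) {
    keep <- !vapply(seq_len(nrow(win)), function(k) {
      any(mask$chrom == win$chrom[k] &
            mask$start < win$end[k] & mask$end > win$start[k])
    }, logical(1))
    win <- win[keep, , drop = FALSE]
  }
  win$window_id <- seq_len(nrow(win))
  dplyr::relocate(win, "window_id")
}

#' Percent identity between two aligned rows
#'
#' The fraction of alignment columns in which both rows carry an unambiguous
#' base (A/C/G/T) and the two bases agree, out of all columns where both rows
#' carry an unambiguous base. Columns where either row is gapped (or N) are
#' excluded from the denominator, so indels are not double-counted as
#' mismatches.
#'
#' @param row_a,row_b Gapped rows of equal length.
#' @return Fraction in `[0, 1]`, or `NA` if no comparable column exists.
#' @export
#' @examples
#' percent_identity("AC-GT", "ACAGA") # columns A/A, C/C, G/G, T/A -> 0.75
percent_identity <- function(row_a, row_b) {
  a <- strsplit(toupper(row_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(row_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("aligned rows have different lengths: ", length(a), " vs ", length(b))
  }
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}

#' Integer-percent divergence of a branch over a window
#'
#' `round(100 * (1 - percent_identity))`, rounding halves up, as an integer
#' percentage point in `[0, 100]`. This is the conditioning variable of the
#' neutral model: transition probabilities are estimated separately for each
#' divergence level.
#'
#' @inheritParams percent_identity
#' @return Integer percent, or `NA` when identity is undefined (the branch
#'   is then excluded from estimation and scoring for this window).
#' @export
divergence <- function(row_a, row_b) {
  pid <- percent_identity(row_a, row_b)
  if (is.na(pid)) return(NA_integer_)
  as.integer(floor(100 * (1 - pid) + 0.5))
}
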