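# Readers for the two motif matrix formats in common use. Matrices may hold
# counts or frequencies; rows summing to ~1 per position are taken as
# frequencies and used as-is (plus pseudocount), anything else as counts.

#' Read PWMs from a TRANSFAC flat file
#'
#' Parses records delimited by `//`. Each record carries an `AC` accession,
#' optionally `ID`/`NA` lines, and a matrix block headed by a `P0` (or `PO`)
#' line naming the base column order, followed by numbered per-position rows
#' (a trailing consensus letter is ignored).
#'
#' @param path Path to a TRANSFAC matrix flat file.
#' @param pseudocount Passed to [pwm()].
#' @return A list of [pwm()] objects, named by identifier.
#' @export
read_transfac <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  if (length(trimws(lines)) == 0L || all(trimws(lines) == "")) {
    stop("empty TRANSFAC file: ", path)
  }
  recs <- split(lines, cumsum(c(0L, head(grepl("^//", lines), -1L))))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    if (all(trimws(rec) == "")) next
    tag <- substr(rec, 1L, 2L)
    val <- trimws(substr(rec, 3L, nchar(rec)))
    ac <- val[tag == "AC"][1]
    nm <- val[tag == "NA"][1]
    if (is.na(ac) && is.na(nm)) ac <- val[tag == "ID"][1]
    ident <- paste(stats::na.omit(c(ac, nm)), collapse = " ")
    if (ident == "") ident <- "<unnamed>"
    p0 <- which(tag %in% c("P0", "PO"))
    if (length(p0) != 1L) {
      if (length(p0) == 0L && !any(grepl("^[0-9]+\\s", rec))) next # no matrix block
      stop("TRANSFAC record '", ident, "': expected exactly one P0 header line")
    }
    order_bases <- strsplit(val[p0], "\\s+")[[1L]]
    if (length(order_bases) != 4L || !setequal(order_bases, DNA_BASES)) {
      stop("TRANSFAC record '", ident, "': P0 line must name the four bases")
    }
    rows <- rec[grepl("^[0-9]+\\s", rec)]
    if (length(rows) == 0L) stop("TRANSFAC record '", ident, "': no matrix rows")
    m <- t(vapply(rows, function(r) {
      f <- strsplit(trimws(r), "\\s+")[[1L]][-1L] # drop position index
      v <- suppressWarnings(as.numeric(f[1:4]))
      if (anyNA(v)) stop("TRANSFAC record '", ident, "': malformed matrix row: ", r)
      v
    }, numeric(4), USE.NAMES = FALSE))
    colnames(m) <- order_bases
    m <- t(m[, DNA_BASES, drop = FALSE]) # 4 x w in A,C,G,T order
    out[[ident]] <- pwm(m, id = ident, pseudocount = pseudocount)
  }
  if (length(out) == 0L) stop("no PWM records found in ", path)
  out
}

#' Read PWMs from a JASPAR PFM file
#'
#' Accepts the JASPAR text format: a `>identifier` header followed by four
#' rows labelled A/C/G/T (in any order), with values optionally wrapped in
#' square brackets. Files containing several matrices are supported.
#'
#' @inheritParams read_transfac
#' @return A list of [pwm()] objects, named by identifier.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) stop("empty JASPAR file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("JASPAR file must start with a '>' header: ", path)
  recs <- split(lines, cumsum(hdr))
  out <- list()
  for (rec in recs) {
    ident <- trimws(sub("^>", "", rec[1L]))
    body <- rec[-1L]
    if (length(body) != 4L) {
      stop("JASPAR record '", ident, "': expected 4 base rows, got ", length(body))
    }
    parsed <- lapply(body, function(r) {
      r <- trimws(r)
      base <- toupper(substr(r, 1L, 1L))
      if (!base %in% DNA_BASES) {
        stop("JASPAR record '", ident, "': row does not start with a base letter: ", r)
      }
      nums <- gsub("[][]", " ", substr(r, 2L, nchar(r)))
      v <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
      if (length(v) == 0L || anyNA(v)) {
        stop("JASPAR record '", ident, "': malformed matrix row: ", r)
      }
      list(base = base, v = v)
    })
    bases <- vapply(parsed, `[[`, character(1), "base")
    if (!setequal(bases, DNA_BASES)) {
      stop("JASPAR record '", ident, "': need one row per base A/C/G/T")
    }
    wlen <- unique(lengths(lapply(parsed, `[[`, "v")))
    if (length(wlen) != 1L) {
      stop("JASPAR record '", ident, "': rows have unequal length")
    }
    m <- do.call(rbind, lapply(parsed, `[[`, "v"))
    rownames(m) <- bases
    m <- m[DNA_BASES, , drop = FALSE]
    out[[ident]] <- pwm(m, id = ident, pseudocount = pseudocount)
  }
  out
}

#' Read PWMs in either supported dialect
#'
#' @inheritParams read_transfac
#' @param dialect `"transfac"` or `"jaspar"`.
#' @return A list of [pwm()] objects.
#' @export
read_matrix <- function(path, dialect = c("transfac", "jaspar"),
                        pseudocount = 0.01) {
  dialect <- match.arg(dialect)
  switch(dialect,
         transfac = read_transfac(path, pseudocount),
         jaspar = read_jaspar(path, pseudocount))
}

#' Persist calibrated thresholds as a tab-separated table
#'
#' @param pwms List of calibrated [pwm()] objects.
#' @param path Output file.
#' @param n_samples,percentile,seed Calibration parameters recorded alongside.
#' @param bg Background used for the information content column.
#' @return The written tibble, invisibly.
#' @export
write_threshold_table <- function(pwms, path, n_samples = 1000L,
                                  percentile = 10, seed = 1L,
                                  bg = background()) {
  tab <- tibble::tibble(
    pwm_id = vapply(pwms, `[[`, character(1), "id"),
    width = vapply(pwms, `[[`, integer(1), "width"),
    info_bits = vapply(pwms, information_content, numeric(1), bg = bg),
    threshold = vapply(pwms, `[[`, numeric(1), "threshold"),
    n_samples = n_samples, percentile = percentile, seed = seed
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
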