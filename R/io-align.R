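# Alignment-block input. Each block is one syntenic gapped alignment over
# all (extant + ancestral) tree nodes that are present, anchored to reference
# genome coordinates (0-based half-open).

new_block_set <- function(df) {
  stopifnot(all(c("block_id", "chrom", "ref_start", "ref_end", "rows")
                %in% names(df)))
  structure(df, class = c("block_set", class(df)))
}

#' Read per-block gapped FASTA alignments
#'
#' The format mirrors what [make_fixture()] writes: blocks introduced by a
#' header comment line
#' `# block id=<n> chrom=<name> start=<0-based> end=<half-open> ref=<node>`
#' followed by one `>node` gapped FASTA record per tree node present in the
#' block. All rows of a block must have equal (gapped) length; coordinates
#' refer to the reference node's gapless sequence.
#'
#' @param path File path.
#' @return A `block_set` tibble: `block_id`, `chrom`, `ref_start`, `ref_end`,
#'   `rows` (list column of named gapped rows).
#' @export
read_alignment_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  starts <- grep("^# block\\b", lines)
  if (length(starts) == 0L) stop("no '# block' headers found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  blocks <- lapply(seq_along(starts), function(i) {
    chunk <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    hdr <- chunk[1L]
    field <- function(key) {
      m <- regmatches(hdr, regexec(paste0("\\b", key, "=(\\S+)"), hdr))[[1L]]
      if (length(m) < 2L) stop("block header missing '", key, "=': ", hdr)
      m[2L]
    }
    body <- chunk[-1L]
    h <- grep("^>", body)
    if (length(h) == 0L) stop("block ", field("id"), " has no sequences")
    ends <- c(h[-1L] - 1L, length(body))
    rows <- vapply(seq_along(h), function(j) {
      paste(body[(h[j] + 1L):ends[j]], collapse = "")
    }, character(1))
    names(rows) <- sub("^>\\s*", "", body[h])
    if (length(unique(nchar(rows))) != 1L) {
      stop("block ", field("id"), ": rows have unequal gapped length")
    }
    tibble::tibble(
      block_id = as.integer(field("id")),
      chrom = field("chrom"),
      ref_start = as.integer(field("start")),
      ref_end = as.integer(field("end")),
      ref = field("ref"),
      rows = list(rows)
    )
  })
  new_block_set(dplyr::bind_rows(blocks))
}

#' Read alignment blocks from a MAF file
#'
#' Parses the UCSC multiple-alignment format: `a` lines open a block and `s`
#' lines carry `src start size strand srcSize text`. The species part of
#' `src` (before the first `.`) is mapped to tree node names through
#' `name_map`; reference coordinates come from the reference species' `s`
#' line, which must be on the `+` strand.
#'
#' @param path MAF file.
#' @param reference Reference species name (after mapping).
#' @param name_map Optional named character vector `c(maf_species = node)`.
#' @return A `block_set` tibble, as [read_alignment_fasta()].
#' @export
read_maf <- function(path, reference, name_map = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & trimws(lines) != ""]
  a_idx <- grep("^a\\b", lines)
  if (length(a_idx) == 0L) stop("no alignment blocks ('a' lines) in ", path)
  bounds <- c(a_idx, length(lines) + 1L)
  blocks <- lapply(seq_along(a_idx), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    s <- chunk[grepl("^s\\s", chunk)]
    if (length(s) == 0L) stop("MAF block ", i, " has no 's' lines")
    parts <- lapply(strsplit(trimws(s), "\\s+"), function(f) {
      if (length(f) < 7L) stop("malformed MAF 's' line: ", paste(f, collapse = " "))
      f
    })
    src <- vapply(parts, `[[`, character(1), 2L)
    species <- sub("\\..*$", "", src)
    chromp <- sub("^[^.]*\\.?", "", src)
    if (!is.null(name_map)) {
      mapped <- unname(name_map[species])
      species <- ifelse(is.na(mapped), species, mapped)
    }
    rows <- vapply(parts, `[[`, character(1), 7L)
    names(rows) <- species
    if (anyDuplicated(species)) {
      stop("MAF block ", i, ": duplicate species after mapping: ",
           paste(species[duplicated(species)], collapse = ", "))
    }
    ri <- match(reference, species)
    if (is.na(ri)) stop("MAF block ", i, ": reference '", reference, "' absent")
    if (parts[[ri]][5L] != "+") {
      stop("MAF block ", i, ": reference row must be on the + strand")
    }
    start <- as.integer(parts[[ri]][3L])
    size <- as.integer(parts[[ri]][4L])
    tibble::tibble(
      block_id = i,
      chrom = if (chromp[ri] == "") "chr" else chromp[ri],
      ref_start = start, ref_end = start + size,
      ref = reference, rows = list(rows)
    )
  })
  new_block_set(dplyr::bind_rows(blocks))
}

#' Read a BED file of intervals
#'
#' BED3+ with 0-based half-open coordinates; extra columns beyond the sixth
#' are ignored, track/browser/comment lines skipped.
#'
#' @param path BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & trimws(lines) != ""]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  # tab-delimited per the BED spec; fall back to whitespace for hand-made files
  f <- if (any(grepl("\t", lines))) strsplit(lines, "\t", fixed = TRUE) else
    strsplit(lines, " +")
  n <- min(lengths(f))
  if (n < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- tibble::tibble(
    chrom = vapply(f, `[[`, character(1), 1L),
    start = as.integer(vapply(f, `[[`, character(1), 2L)),
    end = as.integer(vapply(f, `[[`, character(1), 3L))
  )
  if (n >= 4L) out$name <- vapply(f, `[[`, character(1), 4L)
  if (n >= 5L) out$score <- as.numeric(vapply(f, `[[`, character(1), 5L))
  if (n >= 6L) out$strand <- vapply(f, `[[`, character(1), 6L)
  if (any(out$end <= out$start)) stop("BED interval with end <= start in ", path)
  out
}

#' Write intervals as BED
#'
#' @param df Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` plus any extra columns (written after the first six).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  have <- intersect(cols, names(df))
  extra <- setdiff(names(df), cols)
  out <- df[, c(have, extra), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
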