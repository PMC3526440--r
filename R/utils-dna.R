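#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Encode an uppercase DNA string as integers 1..4 (A,C,G,T); anything else
# (N, IUPAC ambiguity codes, gaps) becomes NA.
encode_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(chars, DNA_BASES)
}

decode_dna <- function(code) {
  paste(DNA_BASES[code], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Ambiguity codes other than N are complemented where defined; `N` and gap
#' characters are preserved in place.
#'
#' @param seq A single DNA string.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("ACGTT")
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Strip gap characters from an aligned row.
ungap <- function(row) gsub("[-.]", "", row)

`%||%` <- function(x, y) if (is.null(x)) y else x
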