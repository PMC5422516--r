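#' IUPAC ambiguity-code algebra
#'
#' Direct Sanger sequencing of a heterozygote shows superimposed peaks at a
#' polymorphic position; the consensus base caller encodes the union of the
#' two alleles as an IUPAC ambiguity code (R = A/G, Y = C/T, S = C/G,
#' W = A/T, K = G/T, M = A/C). `expand_iupac()` maps a code to the set of
#' unambiguous bases it denotes; `collapse_bases()` is its inverse for sets
#' of size 1 and 2 and maps 3- and 4-base sets to the standard codes
#' (B, D, H, V, N).
#'
#' The gap character `"-"` is an alignment state, not a base: it is never a
#' member of a base set and is rejected by both functions.
#'
#' @param code a single IUPAC character (case-insensitive), not `"-"`.
#' @param bases a character vector of unambiguous bases, a subset of
#'   `c("A","C","G","T")`, length 1 to 4.
#' @return `expand_iupac()`: a sorted character vector of bases.
#'   `collapse_bases()`: a single IUPAC character.
#' @examples
#' expand_iupac("S")            # c("C","G")
#' collapse_bases(c("T", "C"))  # "Y"
#' @export
expand_iupac <- function(code) {
  if (length(code) != 1L || !is.character(code) || is.na(code))
    stop("'code' must be a single character")
  code <- toupper(code)
  if (code == "-")
    stop("gap '-' is an alignment state, not a base code")
  bases <- Biostrings::IUPAC_CODE_MAP[code]
  if (is.na(bases))
    stop(sprintf("unknown IUPAC code '%s'", code))
  sort(strsplit(unname(bases), "")[[1L]])
}

#' @rdname expand_iupac
#' @export
collapse_bases <- function(bases) {
  if (length(bases) < 1L)
    stop("empty base set cannot be collapsed")
  bases <- unique(toupper(bases))
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("base set may only contain A, C, G, T")
  key <- paste(sort(bases), collapse = "")
  code <- names(Biostrings::IUPAC_CODE_MAP)[
    match(key, Biostrings::IUPAC_CODE_MAP)]
  code
}

# Degree of ambiguity of a character: 1 for A/C/G/T, 2 for R/Y/S/W/K/M,
# 3 for B/D/H/V, 4 for N, NA for '-'.  Vectorised; used throughout to
# locate heterozygous columns.
iupac_order <- function(chars) {
  n <- nchar(Biostrings::IUPAC_CODE_MAP)[match(chars, names(Biostrings::IUPAC_CODE_MAP))]
  n[chars == "-"] <- NA_integer_
  n
}

# Alphabet accepted in alignments (full IUPAC plus gap).
HYBDIAG_ALPHABET <- c(names(Biostrings::IUPAC_CODE_MAP), "-")

# Hamming distance between two equal-length character vectors; the gap is a
# fifth state, so '-' vs base counts as one difference.
hamming <- function(x, y) sum(x != y)
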