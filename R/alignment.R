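#' Per-locus multiple sequence alignment of population samples
#'
#' A `locus_alignment` holds one aligned locus (nuclear or chloroplast) with
#' one IUPAC-coded consensus row per sample.  Column positions are 1-based
#' throughout the package, so reported diagnostic positions can be read
#' directly off the alignment.
#'
#' @param locus_id short locus name, e.g. `"DUF"` or `"ndhF"`.
#' @param compartment `"nuclear"` or `"chloroplast"`.
#' @param seqs named character vector of aligned sequences (names are sample
#'   IDs).  Case-insensitive input is upper-cased.  Allowed characters:
#'   `A C G T`, the IUPAC ambiguity codes, `N`, and the gap `-`.
#' @return an object of class `locus_alignment` with fields `locus_id`,
#'   `compartment`, `samples`, `seqs` and `length` (aligned columns).
#' @export
locus_alignment <- function(locus_id, compartment = c("nuclear", "chloroplast"),
                            seqs) {
  compartment <- match.arg(compartment)
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named by sample ID")
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate sample IDs in locus %s: %s", locus_id,
                 paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged alignment at locus %s: %s", locus_id,
                 paste(sprintf("%s (%d bp)", names(seqs)[widths != widths[1L]],
                               widths[widths != widths[1L]]), collapse = ", ")))
  if (widths[1L] < 1L) stop("alignment length must be >= 1")
  bad <- !grepl(sprintf("^[%s]*$", paste(HYBDIAG_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    s <- names(seqs)[bad][1L]
    col <- regexpr(sprintf("[^%s]", paste(HYBDIAG_ALPHABET, collapse = "")), seqs[[s]])
    stop(sprintf("invalid character '%s' in sample %s, locus %s, column %d",
                 substr(seqs[[s]], col, col), s, locus_id, col))
  }
  structure(list(locus_id = locus_id, compartment = compartment,
                 samples = names(seqs), seqs = seqs,
                 length = unname(widths[1L])),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s (%s): %d samples x %d bp\n",
              x$locus_id, x$compartment, length(x$samples), x$length))
  invisible(x)
}

# Character matrix view (samples x columns) of an alignment.
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$samples
  m
}

#' Read one aligned locus from a FASTA file
#'
#' Headers are taken as sample IDs (first whitespace-delimited token).
#' Lower-case bases are silently upper-cased.  A ragged alignment or a
#' duplicated sample ID is an error.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @inheritParams locus_alignment
#' @return a [locus_alignment()].
#' @export
read_locus_fasta <- function(path, locus_id = tools::file_path_sans_ext(basename(path)),
                             compartment = c("nuclear", "chloroplast")) {
  compartment <- match.arg(compartment)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  locus_alignment(locus_id, compartment, seqs)
}

#' Write a locus alignment as FASTA
#'
#' @param aln a [locus_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Concatenate loci into one alignment system
#'
#' Appends columns of several loci (same sample set) in the given order,
#' recording per-locus offsets so that concatenated coordinates map back to
#' (locus, 1-based position).  Used for the chloroplast regions, which are
#' uniparentally co-inherited and analysed as one haplotype system.
#'
#' @param alignments list of [locus_alignment()] sharing one sample set.
#' @param compartment optional filter (`"nuclear"` or `"chloroplast"`)
#'   applied before concatenation.
#' @param locus_id name for the combined alignment.
#' @return a `locus_alignment` with an `offsets` attribute
#'   (data.frame `locus_id`, `start`, `end`).
#' @export
concatenate_loci <- function(alignments, compartment = NULL,
                             locus_id = "concat") {
  if (!is.null(compartment))
    alignments <- Filter(function(a) a$compartment == compartment, alignments)
  if (length(alignments) < 1L) stop("no alignments to concatenate")
  samples <- alignments[[1L]]$samples
  for (a in alignments)
    if (!setequal(a$samples, samples))
      stop(sprintf("sample-set mismatch between loci %s and %s",
                   alignments[[1L]]$locus_id, a$locus_id))
  comp <- unique(vapply(alignments, `[[`, "", "compartment"))
  if (length(comp) != 1L)
    stop("cannot concatenate across compartments; pass a compartment filter")
  lens <- vapply(alignments, `[[`, 0L, "length")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seqs <- vapply(samples, function(s)
    paste(vapply(alignments, function(a) unname(a$seqs[[s]]), ""), collapse = ""),
    "")
  out <- locus_alignment(locus_id, comp, seqs)
  attr(out, "offsets") <- data.frame(
    locus_id = vapply(alignments, `[[`, "", "locus_id"),
    start = as.integer(starts), end = as.integer(ends),
    stringsAsFactors = FALSE)
  out
}

#' Map a concatenated coordinate back to its source locus
#'
#' @param concat a concatenated alignment from [concatenate_loci()].
#' @param position 1-based column(s) in the concatenated system.
#' @return data.frame with columns `locus_id` and `position` (1-based within
#'   the source locus).
#' @export
concat_coordinate <- function(concat, position) {
  off <- attr(concat, "offsets")
  if (is.null(off)) stop("alignment has no concatenation offsets")
  i <- findInterval(position, off$start)
  if (any(position < 1L | position > max(off$end)))
    stop("position outside concatenated alignment")
  data.frame(locus_id = off$locus_id[i],
             position = as.integer(position - off$start[i] + 1L),
             stringsAsFactors = FALSE)
}

#' Convert terminal gap runs to missing data
#'
#' Leading and trailing gaps in a per-sample row usually reflect a short
#' sequencing read (a missing flank), not a deletion allele.  This
#' utility rewrites each row's terminal gap runs as `N`, so downstream
#' fixed-difference scans treat those columns as missing data (which
#' disqualifies a column in strict mode) instead of as indel states.
#' Internal gaps are untouched.  Apply before [find_fixed_substitutions()]
#' / [find_fixed_indels()] when flanks are incomplete.
#'
#' @param aln a [locus_alignment()].
#' @return a new `locus_alignment` with terminal gaps recoded as `N`.
#' @export
trim_end_gaps <- function(aln) {
  seqs <- vapply(aln$seqs, function(s) {
    s <- sub("^(-+)", "", s)
    lead <- aln$length - nchar(s)
    s <- sub("(-+)$", "", s)
    trail <- aln$length - lead - nchar(s)
    paste0(strrep("N", lead), s, strrep("N", trail))
  }, "")
  locus_alignment(aln$locus_id, aln$compartment, seqs)
}

#' Sample-to-taxon assignments
#'
#' Maps every sample ID to a taxon label and an analysis role: `parentA`
#' and `parentB` are the two putative parental taxa, `candidate` marks
#' putative hybrids to be scored, `other` covers additional taxa carried
#' through descriptively.  An optional het-indel sidecar records samples
#' whose Sanger consensus showed a heterozygous indel (frame-shifted double
#' peaks downstream of the indel): FASTA cannot encode "allele/gap" in one
#' row, so the row carries the full-length allele and the sidecar the flag.
#'
#' @param assignments data.frame with columns `sample_id`, `taxon`, `role`.
#' @param het_indels optional data.frame with columns `sample_id`,
#'   `locus_id`, `start`, `end` flagging heterozygous indels.
#' @return object of class `taxon_map`.
#' @export
taxon_map <- function(assignments, het_indels = NULL) {
  need <- c("sample_id", "taxon", "role")
  if (!all(need %in% names(assignments)))
    stop("assignments need columns sample_id, taxon, role")
  roles <- c("parentA", "parentB", "candidate", "other")
  if (!all(assignments$role %in% roles))
    stop("role must be one of ", paste(roles, collapse = ", "))
  if (anyDuplicated(assignments$sample_id))
    stop("duplicate sample_id in taxon map")
  for (r in c("parentA", "parentB"))
    if (!any(assignments$role == r))
      stop(sprintf("taxon map must contain at least one %s sample", r))
  if (!is.null(het_indels)) {
    need2 <- c("sample_id", "locus_id", "start", "end")
    if (!all(need2 %in% names(het_indels)))
      stop("het_indels needs columns sample_id, locus_id, start, end")
  }
  structure(list(assignments = assignments[need],
                 het_indels = het_indels),
            class = "taxon_map")
}

#' @export
print.taxon_map <- function(x, ...) {
  tab <- table(x$assignments$role)
  cat("<taxon_map>", nrow(x$assignments), "samples;",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Read a taxon map from TSV
#'
#' Expects columns `sample_id`, `taxon`, `role`; an optional fourth column
#' `het_indels` gives a path (relative to the TSV) to the het-indel sidecar
#' TSV (`sample_id`, `locus_id`, `start`, `end`).
#'
#' @param path TSV file.
#' @return a [taxon_map()].
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  het <- NULL
  if ("het_indels" %in% names(df)) {
    sidecars <- unique(df$het_indels[nzchar(df$het_indels) & !is.na(df$het_indels)])
    if (length(sidecars)) {
      het <- do.call(rbind, lapply(file.path(dirname(path), sidecars),
                                   utils::read.delim,
                                   stringsAsFactors = FALSE))
    }
  }
  taxon_map(df, het)
}

# Samples of a given role (or taxon) from a taxon_map.
samples_of <- function(taxa, role = NULL, taxon = NULL) {
  a <- taxa$assignments
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(taxon)) keep <- keep & a$taxon %in% taxon
  a$sample_id[keep]
}
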