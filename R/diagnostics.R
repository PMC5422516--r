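#' Fixed nucleotide substitutions between the parental taxa
#'
#' A column is a fixed (diagnostic) substitution when every `parentA` sample
#' carries the same unambiguous base, every `parentB` sample carries the
#' same unambiguous base, the two bases differ, and no parental sample has
#' a gap or ambiguity code there.  In strict mode (default) a parental `N`
#' disqualifies the column; lenient mode ignores up to `max_missing_frac`
#' missing parental calls (`N`) per taxon.
#'
#' @param aln a [locus_alignment()].
#' @param taxa a [taxon_map()] covering the alignment's samples.
#' @param min_per_taxon minimum parental samples per taxon for fixation to
#'   be meaningful (default 2; a warning is emitted for 2–4 — the study
#'   design this implements used 18–26 individuals per taxon).
#' @param max_missing_frac fraction of parental `N` calls tolerated per
#'   taxon per column (default 0 = strict).
#' @return data.frame of class `diagnostic_sites` with columns `locus_id`,
#'   `position`, `base_a`, `base_b`, sorted by position.
#' @export
find_fixed_substitutions <- function(aln, taxa, min_per_taxon = 2L,
                                     max_missing_frac = 0) {
  pa <- intersect(aln$samples, samples_of(taxa, "parentA"))
  pb <- intersect(aln$samples, samples_of(taxa, "parentB"))
  check_parental_n(pa, pb, min_per_taxon, aln$locus_id)
  m <- aln_matrix(aln)
  site <- function(rows_a, rows_b, j) {
    a <- fixed_base(rows_a[, j], max_missing_frac)
    if (is.na(a)) return(NULL)
    b <- fixed_base(rows_b[, j], max_missing_frac)
    if (is.na(b) || a == b) return(NULL)
    c(a, b)
  }
  ma <- m[pa, , drop = FALSE]
  mb <- m[pb, , drop = FALSE]
  res <- lapply(seq_len(aln$length), function(j) site(ma, mb, j))
  keep <- !vapply(res, is.null, TRUE)
  out <- data.frame(
    locus_id = rep(aln$locus_id, sum(keep)),
    position = which(keep),
    base_a = vapply(res[keep], `[`, "", 1L),
    base_b = vapply(res[keep], `[`, "", 2L),
    stringsAsFactors = FALSE)
  class(out) <- c("diagnostic_sites", "data.frame")
  out
}

# The single unambiguous base all samples of one taxon carry at a column,
# or NA if the column is not fixed for that taxon.  'N' calls may be
# ignored up to max_missing_frac; gaps and 2-/3-fold ambiguities always
# disqualify.
fixed_base <- function(states, max_missing_frac = 0) {
  n_missing <- sum(states == "N")
  if (n_missing / length(states) > max_missing_frac) return(NA_character_)
  states <- states[states != "N"]
  if (length(states) == 0L) return(NA_character_)
  u <- unique(states)
  if (length(u) == 1L && u %in% c("A", "C", "G", "T")) u else NA_character_
}

check_parental_n <- function(pa, pb, min_per_taxon, locus_id) {
  if (length(pa) < min_per_taxon || length(pb) < min_per_taxon)
    stop(sprintf(
      "locus %s: need >= %d samples per parental taxon (parentA: %d, parentB: %d)",
      locus_id, min_per_taxon, length(pa), length(pb)))
  if (min(length(pa), length(pb)) <= 4L)
    warning(sprintf(
      "locus %s: only %d parental samples in the smaller taxon; fixation calls are weakly supported",
      locus_id, min(length(pa), length(pb))))
}

#' Fixed indels between the parental taxa
#'
#' A fixed indel is a maximal run of columns where every sample of one
#' parental taxon is gapped and every sample of the other carries the same
#' unambiguous bases.  A run of any length counts as one mutational event.
#' The gap run must be identical across all individuals of the gapped
#' taxon: if any gapped-taxon sample's gap extends beyond the shared run
#' (or stops short), the run is not fixed and is dropped.
#'
#' @inheritParams find_fixed_substitutions
#' @return data.frame of class `diagnostic_indels` with columns `locus_id`,
#'   `start`, `end` (1-based inclusive), `present_in` (the taxon carrying
#'   bases: `"parentA"` or `"parentB"`), `inserted_sequence`.
#' @export
find_fixed_indels <- function(aln, taxa, min_per_taxon = 2L) {
  pa <- intersect(aln$samples, samples_of(taxa, "parentA"))
  pb <- intersect(aln$samples, samples_of(taxa, "parentB"))
  check_parental_n(pa, pb, min_per_taxon, aln$locus_id)
  m <- aln_matrix(aln)
  ga <- m[pa, , drop = FALSE] == "-"
  gb <- m[pb, , drop = FALSE] == "-"
  all_gap_a <- apply(ga, 2L, all)
  all_gap_b <- apply(gb, 2L, all)
  any_gap_a <- apply(ga, 2L, any)
  any_gap_b <- apply(gb, 2L, any)

  one_side <- function(all_gap, any_gap_other, m_other, present_in) {
    runs <- runs_of(all_gap)
    sel <- logical(nrow(runs))
    ins <- character(nrow(runs))
    gapped <- if (present_in == "parentA") gb else ga
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- runs$end[i]
      # no gapped-taxon sample may be gapped in the flanking columns
      if (s > 1L && any(gapped[, s - 1L])) next
      if (e < ncol(gapped) && any(gapped[, e + 1L])) next
      # the other taxon carries identical unambiguous bases over the run
      blk <- m_other[, s:e, drop = FALSE]
      if (any(blk == "-" )) next
      if (!all(blk %in% c("A", "C", "G", "T"))) next
      seqs <- apply(blk, 1L, paste, collapse = "")
      if (length(unique(seqs)) != 1L) next
      # no other-taxon sample gapped adjacent (run maximal w.r.t. both taxa)
      sel[i] <- TRUE
      ins[i] <- seqs[[1L]]
    }
    if (!any(sel)) return(NULL)
    data.frame(locus_id = aln$locus_id, start = runs$start[sel],
               end = runs$end[sel], present_in = present_in,
               inserted_sequence = ins[sel], stringsAsFactors = FALSE)
  }

  out <- rbind(one_side(all_gap_b, any_gap_a, m[pa, , drop = FALSE], "parentA"),
               one_side(all_gap_a, any_gap_b, m[pb, , drop = FALSE], "parentB"))
  if (is.null(out))
    out <- data.frame(locus_id = character(), start = integer(),
                      end = integer(), present_in = character(),
                      inserted_sequence = character(), stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_indels", "data.frame")
  out
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end).
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Score a candidate individual for additivity at diagnostic sites
#'
#' At each diagnostic substitution the candidate's IUPAC state is classified
#' as `additive` (it expands to exactly the union of the two parental
#' bases — the chromatogram-additivity signature of a hybrid),
#' `parentA_like`, `parentB_like`, or `other` (including gaps, `N` and 3-fold
#' codes, which can never satisfy a two-parent additivity test).  Each
#' diagnostic indel is classified as `heterozygous` when the candidate is
#' flagged in the het-indel sidecar of the taxon map, otherwise
#' `parentA_like`/`parentB_like` by matching the gapped or full state, else
#' `other`.
#'
#' @param sites `diagnostic_sites` from [find_fixed_substitutions()] (may
#'   span several loci).
#' @param indels `diagnostic_indels` from [find_fixed_indels()], or `NULL`.
#' @param alignments named list of [locus_alignment()] keyed by `locus_id`,
#'   containing the candidate.
#' @param sample_id the candidate sample.
#' @param taxa a [taxon_map()] (supplies the het-indel sidecar).
#' @return an `additivity_report`: list with `sample_id`, `site_verdicts`
#'   (data.frame `locus_id`, `position`, `state`, `verdict`),
#'   `indel_verdicts`, and counts `n_additive`, `n_A`, `n_B`, `n_other`.
#' @export
score_additivity <- function(sites, indels = NULL, alignments, sample_id,
                             taxa = NULL) {
  if (inherits(alignments, "locus_alignment"))
    alignments <- stats::setNames(list(alignments), alignments$locus_id)
  for (a in alignments)
    if (!sample_id %in% a$samples)
      stop(sprintf("candidate %s absent from locus %s", sample_id, a$locus_id))

  verdict_site <- function(locus_id, position, base_a, base_b) {
    ch <- substr(alignments[[locus_id]]$seqs[[sample_id]], position, position)
    if (ch == "-") return(c(ch, "other"))
    bs <- expand_iupac(ch)
    v <- if (length(bs) == 2L && setequal(bs, c(base_a, base_b))) "additive"
    else if (length(bs) == 1L && bs == base_a) "parentA_like"
    else if (length(bs) == 1L && bs == base_b) "parentB_like"
    else "other"
    c(ch, v)
  }
  sv <- if (nrow(sites)) {
    missing_loci <- setdiff(unique(sites$locus_id), names(alignments))
    if (length(missing_loci))
      stop("no alignment supplied for loci: ", paste(missing_loci, collapse = ", "))
    res <- mapply(verdict_site, sites$locus_id, sites$position,
                  sites$base_a, sites$base_b)
    data.frame(locus_id = sites$locus_id, position = sites$position,
               state = res[1L, ], verdict = res[2L, ],
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(locus_id = character(), position = integer(),
                    state = character(), verdict = character())

  het_flags <- if (!is.null(taxa)) taxa$het_indels else NULL
  verdict_indel <- function(locus_id, start, end, present_in, inserted) {
    seg <- substr(alignments[[locus_id]]$seqs[[sample_id]], start, end)
    gap_like <- if (present_in == "parentA") "parentB_like" else "parentA_like"
    full_like <- if (present_in == "parentA") "parentA_like" else "parentB_like"
    flagged <- !is.null(het_flags) &&
      any(het_flags$sample_id == sample_id & het_flags$locus_id == locus_id &
            het_flags$start == start & het_flags$end == end)
    if (flagged) "heterozygous"
    else if (seg == strrep("-", end - start + 1L)) gap_like
    else if (seg == inserted) full_like
    else "other"
  }
  iv <- if (!is.null(indels) && nrow(indels)) {
    data.frame(locus_id = indels$locus_id, start = indels$start,
               end = indels$end,
               verdict = mapply(verdict_indel, indels$locus_id, indels$start,
                                indels$end, indels$present_in,
                                indels$inserted_sequence),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(locus_id = character(), start = integer(),
                    end = integer(), verdict = character())

  structure(list(
    sample_id = sample_id,
    site_verdicts = sv,
    indel_verdicts = iv,
    n_additive = sum(sv$verdict == "additive"),
    n_A = sum(sv$verdict == "parentA_like"),
    n_B = sum(sv$verdict == "parentB_like"),
    n_other = sum(sv$verdict == "other")),
    class = "additivity_report")
}

#' @export
print.additivity_report <- function(x, ...) {
  cat(sprintf("<additivity_report> %s: %d additive, %d parentA-like, %d parentB-like, %d other",
              x$sample_id, x$n_additive, x$n_A, x$n_B, x$n_other))
  if (nrow(x$indel_verdicts))
    cat(sprintf("; indels: %s", paste(x$indel_verdicts$verdict, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Summarise fixed differences across loci
#'
#' @param sites combined `diagnostic_sites` across loci.
#' @param indels combined `diagnostic_indels` across loci.
#' @param loci data.frame with columns `locus_id`, `compartment` giving the
#'   compartment of every analysed locus.
#' @return list with `per_locus` (data.frame `locus_id`, `compartment`,
#'   `n_substitutions`, `n_indels`), `per_compartment`, and grand totals
#'   `total_substitutions`, `total_indels`.
#' @export
summarize_fixed_differences <- function(sites, indels, loci) {
  per_locus <- data.frame(
    locus_id = loci$locus_id,
    compartment = loci$compartment,
    n_substitutions = vapply(loci$locus_id,
                             function(l) sum(sites$locus_id == l), 0L),
    n_indels = vapply(loci$locus_id,
                      function(l) sum(indels$locus_id == l), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  per_comp <- do.call(rbind, lapply(split(per_locus, per_locus$compartment),
    function(d) data.frame(compartment = d$compartment[1L],
                           n_substitutions = sum(d$n_substitutions),
                           n_indels = sum(d$n_indels))))
  rownames(per_comp) <- NULL
  list(per_locus = per_locus,
       per_compartment = per_comp,
       total_substitutions = sum(per_locus$n_substitutions),
       total_indels = sum(per_locus$n_indels))
}
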