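#' Classify an individual from its per-locus additivity evidence
#'
#' Each evaluable nuclear locus is reduced to a genotype class: `AB` when
#' every diagnostic verdict at the locus shows both parental alleles
#' (substitutions `additive`, indels `heterozygous`), `AA`/`BB` when every
#' verdict matches one parent only, and `mixed` otherwise.  The multilocus
#' rule then is: all `AB` = `F1`; `AB` plus `AA` (and no `BB`) =
#' `backcross_A` (mirrored for `backcross_B`); all `AA` = `parentA`; all
#' `BB` = `parentB`; anything else = `complex`.  Any locus with more
#' `other` verdicts than `tolerance` makes the sample `ambiguous`, as does
#' a would-be backcross supported by fewer than two loci (one homozygous
#' parental locus and one `AB` locus are the minimum evidence).
#'
#' Allele dosage is *not* inferred: a Sanger-style consensus cannot
#' distinguish AABB from ABBB in a tetraploid, so classes are defined by
#' allele presence/absence only.
#'
#' @param reports named list of `additivity_report` (one per nuclear
#'   locus) for the sample, from [score_additivity()] run per locus.
#' @param tolerance maximum `other` verdicts tolerated per locus
#'   (default 0).
#' @return list with `sample_id`, `class`, and `locus_classes` (named
#'   character vector).
#' @export
classify_sample <- function(reports, tolerance = 0L) {
  if (length(reports) == 0L) stop("no evaluable loci")
  sample_id <- reports[[1L]]$sample_id
  locus_class <- function(rep) {
    v <- c(rep$site_verdicts$verdict,
           sub("^heterozygous$", "additive", rep$indel_verdicts$verdict))
    if (length(v) == 0L) return(NA_character_)
    if (sum(v == "other") > tolerance) return("other")
    v <- v[v != "other"]
    if (all(v == "additive")) "AB"
    else if (all(v == "parentA_like")) "AA"
    else if (all(v == "parentB_like")) "BB"
    else "mixed"
  }
  lc <- vapply(reports, locus_class, "")
  names(lc) <- vapply(reports, function(r)
    r$site_verdicts$locus_id[1L] %||% names(reports)[1L], "")
  if (!is.null(names(reports))) names(lc) <- names(reports)
  lc <- lc[!is.na(lc)]
  if (length(lc) == 0L) stop("no evaluable loci with diagnostic sites")

  cls <-
    if (any(lc %in% c("other", "mixed"))) {
      if (any(lc == "other")) "ambiguous" else "complex"
    } else if (all(lc == "AB")) "F1"
    else if (all(lc == "AA")) "parentA"
    else if (all(lc == "BB")) "parentB"
    else if (all(lc %in% c("AB", "AA")))
      { if (length(lc) >= 2L) "backcross_A" else "ambiguous" }
    else if (all(lc %in% c("AB", "BB")))
      { if (length(lc) >= 2L) "backcross_B" else "ambiguous" }
    else "complex"
  list(sample_id = sample_id, class = cls, locus_classes = lc)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' Assign the maternal parent from the chloroplast haplotype
#'
#' Chloroplast DNA is maternally inherited in these taxa, so an exact match
#' of the candidate's (concatenated) chloroplast sequence to a parental
#' chloroplast haplotype identifies the seed parent.  A match to a
#' haplotype carried by a single parental individual is still an
#' assignment, with a rare-variant note; a novel haplotype or one shared by
#' both parents yields `unassigned`.
#'
#' @param cp_sequence the candidate's chloroplast sequence.
#' @param inv a [build_inventory()] result containing parental chloroplast
#'   haplotypes.
#' @param parentA_taxon,parentB_taxon taxon labels of the two parents.
#' @return list with `maternal` (`"parentA"`, `"parentB"` or
#'   `"unassigned"`), `note` (`""`, `"rare_variant"`, `"uninformative"` or
#'   `"novel"`), and `matched_label`.
#' @export
assign_maternal <- function(cp_sequence, inv, parentA_taxon, parentB_taxon) {
  d <- inv$inventory
  cp_id <- inv$cp_locus
  if (is.na(cp_id)) stop("inventory contains no chloroplast locus")
  d <- d[d$locus_id == cp_id, ]
  ina <- d[d$taxon == parentA_taxon & d$sequence == cp_sequence, ]
  inb <- d[d$taxon == parentB_taxon & d$sequence == cp_sequence, ]
  if (nrow(ina) && nrow(inb))
    return(list(maternal = "unassigned", note = "uninformative",
                matched_label = NA_character_))
  if (!nrow(ina) && !nrow(inb))
    return(list(maternal = "unassigned", note = "novel",
                matched_label = NA_character_))
  hit <- if (nrow(ina)) ina else inb
  list(maternal = if (nrow(ina)) "parentA" else "parentB",
       note = if (hit$count[1L] == 1L) "rare_variant" else "",
       matched_label = hit$label[1L])
}

#' Partition candidates into clone groups
#'
#' Apomictic (asexual seed) reproduction yields progeny genetically
#' identical to the mother, so candidates with byte-identical multilocus
#' genotypes — both phased nuclear haplotypes at every locus plus the
#' chloroplast haplotype — are consistent with a single clonal lineage.
#' The partition is reported with groups numbered by decreasing size, ties
#' broken by the lexicographically smallest member sample ID.
#'
#' @param inv a [build_inventory()] result covering the candidate samples.
#' @param candidates character vector of candidate sample IDs (>= 2).
#' @return list with `groups` (data.frame `sample_id`, `clone_group`),
#'   `n_groups`, and `single_clone` (`TRUE` when one group covers all
#'   candidates, i.e. the data are consistent with a single apomictic
#'   lineage).
#' @export
assess_clonality <- function(inv, candidates) {
  if (length(candidates) < 2L)
    stop("clonality assessment needs at least two candidate samples")
  p <- inv$pairs[inv$pairs$sample_id %in% candidates, ]
  key <- vapply(candidates, function(s) {
    rows <- p[p$sample_id == s, ]
    rows <- rows[order(rows$locus_id), ]
    paste(vapply(seq_len(nrow(rows)), function(i) {
      h <- sort(c(rows$hap1[i], rows$hap2[i]), na.last = TRUE)
      paste(rows$locus_id[i], paste(h, collapse = "|"), sep = ":")
    }, ""), collapse = ";")
  }, "")
  grp <- split(candidates, key)
  ordr <- order(-lengths(grp), vapply(grp, function(g) sort(g)[1L], ""))
  grp <- grp[ordr]
  groups <- data.frame(
    sample_id = unlist(grp, use.names = FALSE),
    clone_group = rep(seq_along(grp), lengths(grp)),
    stringsAsFactors = FALSE)
  groups <- groups[order(groups$sample_id), ]
  rownames(groups) <- NULL
  list(groups = groups, n_groups = length(grp),
       single_clone = length(grp) == 1L)
}

#' Full per-sample verdicts for all candidate individuals
#'
#' Convenience wrapper combining [classify_sample()], [assign_maternal()]
#' and [assess_clonality()] over every `candidate` sample of a dataset.
#'
#' @param alignments named list of [locus_alignment()].
#' @param taxa a [taxon_map()]; roles `parentA`/`parentB` define the
#'   diagnostic contrast and `candidate` the samples to call.
#' @param parentA_taxon,parentB_taxon taxon labels of the parents (default:
#'   taken from the roles).
#' @param min_per_taxon,max_het,tolerance forwarded thresholds.
#' @return data.frame of class `hybrid_calls`: `sample_id`, `class`,
#'   `maternal`, `maternal_note`, `clone_group`.
#' @export
classify_all <- function(alignments, taxa,
                         parentA_taxon = NULL, parentB_taxon = NULL,
                         min_per_taxon = 2L, max_het = 12L, tolerance = 0L) {
  amap <- taxa$assignments
  if (is.null(parentA_taxon))
    parentA_taxon <- unique(amap$taxon[amap$role == "parentA"])[1L]
  if (is.null(parentB_taxon))
    parentB_taxon <- unique(amap$taxon[amap$role == "parentB"])[1L]
  candidates <- samples_of(taxa, "candidate")
  if (!length(candidates)) {
    out <- data.frame(sample_id = character(), class = character(),
                      maternal = character(), maternal_note = character(),
                      clone_group = integer(), stringsAsFactors = FALSE)
    class(out) <- c("hybrid_calls", "data.frame")
    return(out)
  }
  comp <- vapply(alignments, `[[`, "", "compartment")
  nuc <- alignments[comp == "nuclear"]
  sites <- lapply(nuc, find_fixed_substitutions, taxa = taxa,
                  min_per_taxon = min_per_taxon)
  indels <- lapply(nuc, find_fixed_indels, taxa = taxa,
                   min_per_taxon = min_per_taxon)
  inv <- build_inventory(alignments, taxa, max_het = max_het)

  cp_seq_of <- function(s) {
    p <- inv$pairs
    p$hap1[p$sample_id == s & p$locus_id == inv$cp_locus][1L]
  }
  calls <- lapply(candidates, function(s) {
    reports <- list()
    for (l in names(nuc)) {
      if (nrow(sites[[l]]) == 0L && nrow(indels[[l]]) == 0L) next
      reports[[l]] <- score_additivity(sites[[l]], indels[[l]], nuc[[l]],
                                       s, taxa)
    }
    cl <- classify_sample(reports, tolerance = tolerance)
    mat <- if (!is.na(inv$cp_locus))
      assign_maternal(cp_seq_of(s), inv, parentA_taxon, parentB_taxon)
    else list(maternal = "unassigned", note = "no_cp_data")
    data.frame(sample_id = s, class = cl$class, maternal = mat$maternal,
               maternal_note = mat$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  if (length(candidates) >= 2L) {
    cg <- assess_clonality(inv, candidates)
    out$clone_group <- cg$groups$clone_group[match(out$sample_id,
                                                   cg$groups$sample_id)]
  } else out$clone_group <- 1L
  rownames(out) <- NULL
  class(out) <- c("hybrid_calls", "data.frame")
  out
}
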