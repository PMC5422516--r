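#' The Cotoneaster dielsianus x C. glaucophyllus reference dataset
#'
#' The package bundles, as code, the published diagnostic-site states of
#' the hybrid system this pipeline was designed around: five low-copy
#' nuclear genes (DUF, NA1, NA2, UPF, WD) and six chloroplast regions
#' (ndhF, rpl16, rps16, trnC-ycf6, trnG-trnS, trnH-rpl2) sequenced for
#' population samples of *C. dielsianus* (tetraploid), *C. glaucophyllus*
#' (diploid), their putative hybrid, and *C. franchetii*.  The two parents
#' are separated by 36 fixed nuclear substitutions plus one fixed 6-bp
#' indel and 14 chloroplast substitutions plus three fixed indels; the
#' hybrid shows IUPAC additivity at every fixed difference and carries the
#' minor *C. glaucophyllus* chloroplast haplotype.
#'
#' `cotoneaster_sites()` returns the per-taxon states at the diagnostic
#' substitution columns; `cotoneaster_loci()` the locus metadata;
#' `cotoneaster_indels()` the fixed indel events;
#' `cotoneaster_alignments()` expands these into full population
#' alignments (monomorphic away from the tabulated columns, with the
#' within-taxon haplotype variants placed at non-diagnostic columns so the
#' published per-taxon haplotype counts are reproduced).  A handful of
#' published chloroplast column labels are typographically unreliable and
#' are treated as nominal positions; counts and states are preserved.
#'
#' @return `cotoneaster_sites()`: data.frame `locus_id`, `position`,
#'   `hybrid`, `dielsianus`, `glaucophyllus`, `franchetii`.
#' @name cotoneaster
NULL

#' @rdname cotoneaster
#' @export
cotoneaster_loci <- function() {
  data.frame(
    locus_id = c("DUF", "NA1", "NA2", "UPF", "WD",
                 "ndhF", "rpl16", "rps16", "trnC-ycf6", "trnG-trnS",
                 "trnH-rpl2"),
    compartment = rep(c("nuclear", "chloroplast"), c(5L, 6L)),
    length = c(840L, 568L, 461L, 645L, 811L,
               1036L, 891L, 662L, 648L, 415L, 316L),
    stringsAsFactors = FALSE)
}

#' @rdname cotoneaster
#' @export
cotoneaster_sites <- function() {
  st <- function(locus, pos, hy, di, gl, fr)
    data.frame(locus_id = locus, position = pos,
               hybrid = strsplit(hy, "")[[1L]],
               dielsianus = strsplit(di, "")[[1L]],
               glaucophyllus = strsplit(gl, "")[[1L]],
               franchetii = strsplit(fr, "")[[1L]],
               stringsAsFactors = FALSE)
  rbind(
    st("DUF", c(66L, 117L, 266L, 285L, 412L, 454L, 532L, 571L, 581L,
                607L, 649L, 672L, 766L, 810L),
       "SWYWYYRYSYRWYK", "GATACTACGCAACG", "CTCTTCGTCTGTTT", "SAYWYYRYSYRTCK"),
    st("NA1", c(379L, 397L, 435L, 443L),
       "YKWK", "CTAG", "TGTT", "YKWK"),
    st("NA2", c(149L, 215L, 268L, 340L, 408L),
       "RYKSR", "GCTCG", "ATGGA", "RYKSR"),
    st("UPF", c(517L, 520L, 521L, 525L, 526L, 527L),
       "RRRWWR", "GAATAG", "AGGATA", "RRRWWR"),
    st("WD", c(187L, 195L, 257L, 278L, 364L, 623L, 625L),
       "YYRWMKK", "CCATAGG", "TTGACTT", "CCATMKK"),
    st("ndhF", c(379L, 716L), "AC", "TA", "AC", "AC"),
    st("rpl16", c(582L, 589L, 635L, 679L), "GTGT", "TGAC", "GTGT", "TGAT"),
    st("rps16", c(65L, 125L, 593L), "TGA", "CTG", "TGA", "TGA"),
    st("trnC-ycf6", c(109L, 188L, 344L), "CGT", "GTC", "CGT", "CGT"),
    st("trnG-trnS", 219L, "T", "C", "T", "T"),
    st("trnH-rpl2", 254L, "C", "T", "C", "C"))
}

#' @rdname cotoneaster
#' @export
cotoneaster_indels <- function() {
  # fixed indel events between the parents: 'present_in' names the taxon
  # carrying bases; the hybrid is heterozygous at the nuclear WD indel
  # (full allele in the row + het sidecar), and C. franchetii likewise.
  data.frame(
    locus_id = c("WD", "rpl16", "trnG-trnS", "trnH-rpl2"),
    start = c(40L, 700L, 191L, 59L),
    end = c(45L, 700L, 208L, 71L),
    present_in = c("glaucophyllus", "glaucophyllus", "glaucophyllus",
                   "glaucophyllus"),
    inserted_sequence = c("TCACAT", "T", "TTATTCCTTTTATTTTAG",
                          "ATTTAATATAAAT"),
    franchetii = c("het", "gap", "bases", "bases"),
    stringsAsFactors = FALSE)
}

# Within-taxon haplotype variants (single-substitution neighbours of the
# taxon founder at non-diagnostic columns), reproducing the published
# per-taxon haplotype counts: C. dielsianus 2/2/1/2/1 nuclear + 1 cp = 9,
# C. glaucophyllus 1/3/2/1/1 + 2 cp = 10.  'carrier' is the 1-based index
# of the carrying sample within its taxon.
cotoneaster_variants <- function() {
  data.frame(
    taxon = c("C_dielsianus", "C_dielsianus", "C_dielsianus",
              "C_glaucophyllus", "C_glaucophyllus", "C_glaucophyllus",
              "C_glaucophyllus"),
    locus_id = c("DUF", "NA1", "UPF", "NA1", "NA1", "NA2", "ndhF"),
    position = c(10L, 10L, 10L, 20L, 24L, 20L, 500L),
    alt = c("A", "A", "A", "C", "G", "C", "G"),
    carrier = c(1L, 1L, 1L, 1L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
}

# Deterministic monomorphic background: base depends only on the column.
background_seq <- function(len) c("A", "C", "G", "T")[(seq_len(len) %% 4L) + 1L]

#' @rdname cotoneaster
#' @param n_hybrid,n_dielsianus,n_franchetii,n_glaucophyllus samples per
#'   taxon (defaults mirror the study's sampling: 30 putative hybrids, 18
#'   *C. dielsianus*, 22 *C. franchetii*, 26 *C. glaucophyllus*).
#' @return `cotoneaster_alignments()`: list with `alignments` (named list
#'   of [locus_alignment()]) and `taxa` (a [taxon_map()] whose het-indel
#'   sidecar flags the hybrid and *C. franchetii* samples at the WD indel).
#' @export
cotoneaster_alignments <- function(n_hybrid = 30L, n_dielsianus = 18L,
                                   n_franchetii = 22L, n_glaucophyllus = 26L) {
  loci <- cotoneaster_loci()
  sites <- cotoneaster_sites()
  indels <- cotoneaster_indels()
  variants <- cotoneaster_variants()

  ids <- list(
    hybrid = sprintf("13917_%02d", seq_len(n_hybrid)),
    C_dielsianus = sprintf("13916_%02d", n_hybrid + seq_len(n_dielsianus)),
    C_franchetii = sprintf("13915_%02d",
                           n_hybrid + n_dielsianus + seq_len(n_franchetii)),
    C_glaucophyllus = sprintf("13949_%02d",
                              n_hybrid + n_dielsianus + n_franchetii +
                                seq_len(n_glaucophyllus)))

  alignments <- list()
  het_rows <- list()
  for (i in seq_len(nrow(loci))) {
    lid <- loci$locus_id[i]
    len <- loci$length[i]
    bg <- background_seq(len)
    s <- sites[sites$locus_id == lid, ]
    ev <- indels[indels$locus_id == lid, ]

    make_row <- function(states_col) {
      r <- bg
      r[s$position] <- s[[states_col]]
      r
    }
    di <- make_row("dielsianus")
    gl <- make_row("glaucophyllus")
    hy <- make_row("hybrid")
    fr <- make_row("franchetii")
    for (k in seq_len(nrow(ev))) {
      rng <- ev$start[k]:ev$end[k]
      ins <- strsplit(ev$inserted_sequence[k], "")[[1L]]
      gl[rng] <- ins
      di[rng] <- "-"
      hy[rng] <- ins  # full allele in the row; het flagged in the sidecar
      fr[rng] <- switch(ev$franchetii[k],
                        het = ins, bases = ins, gap = rep("-", length(rng)))
      if (ev$franchetii[k] == "het")
        het_rows[[length(het_rows) + 1L]] <- data.frame(
          sample_id = ids$C_franchetii, locus_id = lid,
          start = ev$start[k], end = ev$end[k], stringsAsFactors = FALSE)
      if (loci$compartment[i] == "nuclear")
        het_rows[[length(het_rows) + 1L]] <- data.frame(
          sample_id = ids$hybrid, locus_id = lid,
          start = ev$start[k], end = ev$end[k], stringsAsFactors = FALSE)
    }
    if (lid == "trnH-rpl2") fr[100:109] <- "-"  # franchetii-private deletion

    rows <- c(
      stats::setNames(rep(paste(hy, collapse = ""), n_hybrid), ids$hybrid),
      stats::setNames(rep(paste(di, collapse = ""), n_dielsianus),
                      ids$C_dielsianus),
      stats::setNames(rep(paste(fr, collapse = ""), n_franchetii),
                      ids$C_franchetii),
      stats::setNames(rep(paste(gl, collapse = ""), n_glaucophyllus),
                      ids$C_glaucophyllus))

    v <- variants[variants$locus_id == lid, ]
    for (k in seq_len(nrow(v))) {
      carrier <- ids[[v$taxon[k]]][v$carrier[k]]
      if (is.na(carrier)) next
      row <- strsplit(rows[[carrier]], "")[[1L]]
      row[v$position[k]] <- v$alt[k]
      rows[[carrier]] <- paste(row, collapse = "")
    }
    # the hybrid chloroplast is the minor C. glaucophyllus haplotype (H_A)
    if (lid == "ndhF") {
      ha <- strsplit(rows[[ids$C_glaucophyllus[1L]]], "")[[1L]]
      for (h in ids$hybrid) rows[[h]] <- paste(ha, collapse = "")
    }
    alignments[[lid]] <- locus_alignment(lid, loci$compartment[i], rows)
  }

  assignments <- data.frame(
    sample_id = unlist(ids, use.names = FALSE),
    taxon = rep(c("hybrid", "C_dielsianus", "C_franchetii",
                  "C_glaucophyllus"), lengths(ids)),
    role = rep(c("candidate", "parentA", "other", "parentB"), lengths(ids)),
    stringsAsFactors = FALSE)
  het <- do.call(rbind, het_rows)
  list(alignments = alignments, taxa = taxon_map(assignments, het))
}

#' Write the reference dataset to disk
#'
#' Emits the per-locus FASTA files, the locus metadata TSV, the taxon map
#' TSV with its het-indel sidecar, and the published flow-cytometry
#' parameters (2C values), in the dialects the pipeline consumes.
#'
#' @param dir output directory (created if missing).
#' @param ... forwarded to [cotoneaster_alignments()].
#' @return `dir`, invisibly.
#' @export
write_cotoneaster_dataset <- function(dir, ...) {
  fx <- cotoneaster_alignments(...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- cotoneaster_loci()
  loci$file <- paste0(loci$locus_id, ".fasta")
  for (i in seq_len(nrow(loci)))
    write_locus_fasta(fx$alignments[[loci$locus_id[i]]],
                      file.path(dir, loci$file[i]))
  utils::write.table(loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  amap <- fx$taxa$assignments
  amap$het_indels <- "het_indels.tsv"
  utils::write.table(amap, file.path(dir, "taxon_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$taxa$het_indels, file.path(dir, "het_indels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  flow <- data.frame(taxon = c("C_dielsianus", "hybrid", "C_glaucophyllus"),
                     mean_2c_pg = c(2.05, 2.02, 1.09),
                     ploidy = c(4L, 4L, 2L), stringsAsFactors = FALSE)
  utils::write.table(flow, file.path(dir, "flow_reference.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
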