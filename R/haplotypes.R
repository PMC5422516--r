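#' Phase an IUPAC-coded genotype row into a haplotype pair
#'
#' Deterministic parsimony anchoring: the heterozygous items of the row —
#' its 2-fold IUPAC columns, plus any heterozygous indel runs flagged in
#' the het-indel sidecar (where one chromosome carries the allele the row
#' shows and the other a gap) — admit `2^(k-1)` distinct haplotype pairs;
#' the pair returned is the unique one minimising the summed Hamming
#' distance of each member to its closest parental reference haplotype.
#' When the minimiser is not unique the row is flagged `unphaseable`
#' rather than guessed.  Rows containing 3-fold codes or `N` are flagged
#' `unphaseable` as well — a two-allele model cannot resolve them.
#'
#' Columns that are not heterozygous contribute the same distance under
#' every phasing, so distances are evaluated over the heterozygous items
#' only (plus a constant), keeping the enumeration cheap.
#'
#' @param genotype a single aligned sequence (character scalar).
#' @param parental_haplotypes character vector of reference haplotypes of
#'   the same aligned length (typically the parental haplotypes at the
#'   locus).
#' @param max_het cap on the number of heterozygous items enumerated
#'   (default 12); above the cap the call refuses rather than run an
#'   exponential search.
#' @param het_runs optional data.frame with columns `start`, `end`: indel
#'   runs at which this row is heterozygous (the row carries the
#'   full-length allele; one phased haplotype receives the gap run).
#' @return list with `haplotypes` (character vector of length 2, sorted)
#'   and `status` (`"phased"`, `"homozygous"`, or `"unphaseable"`); for
#'   `"unphaseable"` the haplotypes are `NA`.
#' @export
phase_sample <- function(genotype, parental_haplotypes, max_het = 12L,
                         het_runs = NULL) {
  genotype <- toupper(genotype)
  chars <- strsplit(genotype, "")[[1L]]
  ord <- iupac_order(chars)
  if (any(!is.na(ord) & ord > 2L))
    return(list(haplotypes = c(NA_character_, NA_character_),
                status = "unphaseable"))
  het <- which(!is.na(ord) & ord == 2L)
  n_runs <- if (is.null(het_runs)) 0L else nrow(het_runs)
  k <- length(het) + n_runs
  if (k == 0L)
    return(list(haplotypes = c(genotype, genotype), status = "homozygous"))
  if (k > max_het)
    stop(sprintf("%d heterozygous items exceed the enumeration cap (%d)",
                 k, max_het))
  if (length(parental_haplotypes) == 0L)
    stop("at least one parental reference haplotype is required")
  refs <- strsplit(toupper(parental_haplotypes), "")
  if (any(lengths(refs) != length(chars)))
    stop("reference haplotypes must match the genotype's aligned length")
  n_ref <- length(refs)

  # heterozygous items: substitution columns (two bases) and indel runs
  # (full allele vs gap run); each item has two variants with, for every
  # reference, a precomputed distance contribution
  run_cols <- integer()
  items <- lapply(het, function(j) {
    al <- expand_iupac(chars[j])
    list(cols = j, v1 = al[1L], v2 = al[2L],
         d1 = vapply(refs, function(r) as.integer(r[j] != al[1L]), 0L),
         d2 = vapply(refs, function(r) as.integer(r[j] != al[2L]), 0L))
  })
  if (n_runs > 0L) {
    for (i in seq_len(n_runs)) {
      cols <- het_runs$start[i]:het_runs$end[i]
      allele <- chars[cols]
      gap <- rep("-", length(cols))
      items[[length(items) + 1L]] <- list(
        cols = cols, v1 = allele, v2 = gap,
        d1 = vapply(refs, function(r) sum(r[cols] != allele), 0L),
        d2 = vapply(refs, function(r) sum(r[cols] != gap), 0L))
      run_cols <- c(run_cols, cols)
    }
  }

  # constant distance of the homozygous backbone to each reference
  hom <- setdiff(seq_along(chars), c(het, run_cols))
  base_d <- vapply(refs, function(r) sum(r[hom] != chars[hom]), 0L)

  build_hap <- function(take_first) {
    h <- chars
    for (i in seq_len(k))
      h[items[[i]]$cols] <- if (take_first[i]) items[[i]]$v1 else items[[i]]$v2
    paste(h, collapse = "")
  }

  # vectorised enumeration: picks is 2^(k-1) x k (first item fixed to its
  # first variant, halving the search: swapping the two members gives the
  # same unordered pair).  Distance of member m to reference r is
  # base_d[r] + sum over items of the chosen variant's contribution.
  D1 <- do.call(rbind, lapply(items, `[[`, "d1"))  # k x n_ref
  D2 <- do.call(rbind, lapply(items, `[[`, "d2"))
  picks <- if (k == 1L) matrix(1, 1L, 1L)
  else cbind(1, as.matrix(expand.grid(rep(list(c(1, 0)), k - 1L),
                                      KEEP.OUT.ATTRS = FALSE)))
  m1 <- picks %*% (D1 - D2) +
    matrix(base_d + colSums(D2), nrow(picks), n_ref, byrow = TRUE)
  m2 <- (1 - picks) %*% (D1 - D2) +
    matrix(base_d + colSums(D2), nrow(picks), n_ref, byrow = TRUE)
  sc <- apply(m1, 1L, min) + apply(m2, 1L, min)
  hits <- which(sc == min(sc))
  # distinct picks always yield distinct unordered pairs, so a unique
  # minimiser is exactly a unique best phasing
  if (length(hits) > 1L)
    return(list(haplotypes = c(NA_character_, NA_character_),
                status = "unphaseable"))
  pick <- picks[hits, ] == 1
  list(haplotypes = sort(c(build_hap(pick), build_hap(!pick))),
       status = "phased")
}

#' Build per-taxon, per-locus haplotype inventories
#'
#' Nuclear loci are phased: parental reference haplotypes are the distinct
#' fully homozygous rows of each parental taxon; heterozygous rows (of any
#' taxon) are then phased against the pooled parental references with
#' [phase_sample()], honouring the het-indel sidecar of the taxon map.
#' Chloroplast loci are concatenated first and treated as one haploid
#' haplotype system — an ambiguity code in a chloroplast row is a data
#' error, not a heterozygote.  Haplotype labels (`H1`, `H2`, ...) are
#' assigned per locus in order of decreasing carrier count, ties broken
#' lexicographically by sequence, so outputs are stable across runs.
#'
#' @param alignments named list of [locus_alignment()].
#' @param taxa a [taxon_map()].
#' @param max_het phasing cap passed to [phase_sample()].
#' @return object of class `haplotype_inventory`: list with
#'   `inventory` (data.frame `taxon`, `locus_id`, `label`, `count`,
#'   `sequence`), `pairs` (data.frame `sample_id`, `taxon`, `locus_id`,
#'   `hap1`, `hap2`, `status`), and `cp_locus` (the concatenated
#'   chloroplast locus id, or `NA`).
#' @export
build_inventory <- function(alignments, taxa, max_het = 12L) {
  if (inherits(alignments, "locus_alignment"))
    alignments <- stats::setNames(list(alignments), alignments$locus_id)
  comp <- vapply(alignments, `[[`, "", "compartment")
  nuc <- alignments[comp == "nuclear"]
  cp <- alignments[comp == "chloroplast"]
  cp_locus <- NA_character_
  if (length(cp) > 1L) {
    cc <- concatenate_loci(cp, locus_id = "cp")
    cp <- stats::setNames(list(cc), "cp")
    cp_locus <- "cp"
  } else if (length(cp) == 1L) {
    cp_locus <- cp[[1L]]$locus_id
  }

  amap <- taxa$assignments
  taxon_of <- stats::setNames(amap$taxon, amap$sample_id)
  het_of <- function(s, locus_id) {
    h <- taxa$het_indels
    if (is.null(h)) return(NULL)
    h <- h[h$sample_id == s & h$locus_id == locus_id, c("start", "end")]
    if (nrow(h)) h else NULL
  }

  pairs <- list()
  for (aln in nuc) {
    refs <- parental_references(aln, taxa)
    cache <- new.env(parent = emptyenv())
    for (s in aln$samples) {
      runs <- het_of(s, aln$locus_id)
      key <- paste(aln$seqs[[s]],
                   paste(runs$start, runs$end, collapse = ","), sep = "|")
      ph <- if (!is.null(cache[[key]])) cache[[key]]
      else cache[[key]] <- phase_sample(aln$seqs[[s]], refs,
                                        max_het = max_het, het_runs = runs)
      pairs[[length(pairs) + 1L]] <- data.frame(
        sample_id = s, taxon = unname(taxon_of[s]), locus_id = aln$locus_id,
        hap1 = ph$haplotypes[1L], hap2 = ph$haplotypes[2L],
        status = if (ph$status == "homozygous") "phased" else ph$status,
        stringsAsFactors = FALSE)
    }
  }
  for (aln in cp) {
    for (s in aln$samples) {
      row <- aln$seqs[[s]]
      ord <- iupac_order(strsplit(row, "")[[1L]])
      if (any(!is.na(ord) & ord > 1L))
        stop(sprintf(
          "chloroplast row for sample %s contains ambiguity codes; cpDNA is treated as haploid",
          s))
      pairs[[length(pairs) + 1L]] <- data.frame(
        sample_id = s, taxon = unname(taxon_of[s]), locus_id = aln$locus_id,
        hap1 = row, hap2 = NA_character_, status = "haploid",
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)

  inv <- list()
  for (key in split(pairs, list(pairs$taxon, pairs$locus_id), drop = TRUE)) {
    seqs <- c(key$hap1, key$hap2)
    seqs <- seqs[!is.na(seqs)]
    if (!length(seqs)) next
    tab <- table(seqs)
    ordr <- order(-as.integer(tab), names(tab))
    inv[[length(inv) + 1L]] <- data.frame(
      taxon = key$taxon[1L], locus_id = key$locus_id[1L],
      label = paste0("H", seq_along(tab)),
      count = as.integer(tab)[ordr],
      sequence = names(tab)[ordr], stringsAsFactors = FALSE)
  }
  inv <- do.call(rbind, inv)
  rownames(inv) <- NULL
  structure(list(inventory = inv, pairs = pairs, cp_locus = cp_locus),
            class = "haplotype_inventory")
}

#' @export
print.haplotype_inventory <- function(x, ...) {
  tab <- stats::aggregate(label ~ taxon, data = x$inventory, FUN = length)
  cat("<haplotype_inventory>",
      paste(sprintf("%s: %d haplotypes", tab$taxon, tab$label), collapse = "; "),
      "\n")
  invisible(x)
}

# Distinct fully homozygous rows of the two parental taxa at a locus.
parental_references <- function(aln, taxa) {
  par <- intersect(aln$samples, samples_of(taxa, c("parentA", "parentB")))
  rows <- aln$seqs[par]
  hom <- vapply(rows, function(r) {
    ord <- iupac_order(strsplit(r, "")[[1L]])
    !any(!is.na(ord) & ord > 1L)
  }, TRUE)
  unique(unname(rows[hom]))
}

#' Haplotypes shared between two taxa
#'
#' Sharing is exact sequence identity within a locus.
#'
#' @param inv a [build_inventory()] result.
#' @param taxon1,taxon2 taxon labels.
#' @return data.frame `locus_id`, `sequence`, `label1`, `label2` (one row
#'   per shared haplotype; zero rows when none are shared).
#' @export
shared_haplotypes <- function(inv, taxon1, taxon2) {
  d <- inv$inventory
  a <- d[d$taxon == taxon1, ]
  b <- d[d$taxon == taxon2, ]
  m <- merge(a, b, by = c("locus_id", "sequence"), suffixes = c("1", "2"))
  out <- m[order(m$locus_id), c("locus_id", "sequence", "label1", "label2")]
  rownames(out) <- NULL
  out
}
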