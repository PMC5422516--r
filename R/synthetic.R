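# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic study-design generator
#'
#' Defaults emulate the sampling design the pipeline was built around: two
#' parental taxa separated by configurable numbers of fixed substitutions
#' and fixed indels at 5 nuclear + 6 chloroplast loci, shallow
#' within-taxon haplotype diversity (variants are single-substitution
#' neighbours of each taxon founder), 18 and 26 parental samples, and 30
#' candidate individuals that are apomictic clones of a single F1 whose
#' maternal parent is parentB.
#'
#' @param loci data.frame with columns `locus_id`, `compartment`, `length`,
#'   `n_substitutions` (fixed substitutions between the parents) and
#'   `indel_lengths` (list-column of fixed-indel lengths, possibly empty).
#' @param hap_counts data.frame `taxon` (`parentA`/`parentB`), `locus_id`,
#'   `n` — number of distinct haplotypes per taxon per locus (>= 1).
#' @param n_parentA,n_parentB parental sample sizes.
#' @param n_f1_clones,n_f1_independent,n_backcross_A,n_backcross_B,n_parental_mislabeled
#'   candidate composition (mislabeled parentals are pure parentA
#'   individuals carried with role `candidate`).
#' @param maternal maternal parent of the F1s (`"parentA"` or `"parentB"`).
#' @param dropout_rate per-heterozygous-site probability that the consensus
#'   drops one allele (genotyping noise; default 0).
#' @param flow data.frame `taxon`, `mean_2c_pg` plus scalars below, used by
#'   [simulate_flow()].
#' @param flow_cv,flow_events,standard_2c flow-peak coefficient of
#'   variation, events per stream, and internal-standard 2C (pg).
#' @param diag_positions optional named list (by `locus_id`) of explicit
#'   diagnostic positions; validated against variant positions (a
#'   collision is an error).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    loci = NULL, hap_counts = NULL,
    n_parentA = 18L, n_parentB = 26L,
    n_f1_clones = 30L, n_f1_independent = 0L,
    n_backcross_A = 0L, n_backcross_B = 0L,
    n_parental_mislabeled = 0L,
    maternal = "parentB", dropout_rate = 0,
    flow = NULL, flow_cv = 0.03, flow_events = 10000L, standard_2c = 2.5,
    diag_positions = NULL) {
  if (is.null(loci)) {
    loci <- data.frame(
      locus_id = c("DUF", "NA1", "NA2", "UPF", "WD",
                   "ndhF", "rpl16", "rps16", "trnC-ycf6", "trnG-trnS",
                   "trnH-rpl2"),
      compartment = rep(c("nuclear", "chloroplast"), c(5L, 6L)),
      length = c(840L, 568L, 461L, 645L, 811L,
                 1036L, 891L, 662L, 648L, 415L, 316L),
      n_substitutions = c(14L, 4L, 6L, 5L, 7L, 2L, 4L, 3L, 3L, 1L, 1L),
      stringsAsFactors = FALSE)
    loci$indel_lengths <- list(integer(), integer(), integer(), integer(),
                               6L, integer(), 1L, integer(), integer(),
                               18L, 13L)
  }
  if (is.null(hap_counts)) {
    hap_counts <- rbind(
      data.frame(taxon = "parentA",
                 locus_id = c("DUF", "NA1", "NA2", "UPF", "WD", "cp"),
                 n = c(2L, 2L, 1L, 2L, 1L, 1L), stringsAsFactors = FALSE),
      data.frame(taxon = "parentB",
                 locus_id = c("DUF", "NA1", "NA2", "UPF", "WD", "cp"),
                 n = c(1L, 3L, 2L, 1L, 1L, 2L), stringsAsFactors = FALSE))
  }
  if (is.null(flow))
    flow <- data.frame(taxon = c("parentA", "F1", "parentB"),
                       mean_2c_pg = c(2.05, 2.02, 1.09),
                       stringsAsFactors = FALSE)
  stopifnot(maternal %in% c("parentA", "parentB"),
            all(hap_counts$n >= 1L), dropout_rate >= 0, dropout_rate <= 1)
  structure(list(loci = loci, hap_counts = hap_counts,
                 n_parentA = n_parentA, n_parentB = n_parentB,
                 n_f1_clones = n_f1_clones,
                 n_f1_independent = n_f1_independent,
                 n_backcross_A = n_backcross_A,
                 n_backcross_B = n_backcross_B,
                 n_parental_mislabeled = n_parental_mislabeled,
                 maternal = maternal, dropout_rate = dropout_rate,
                 flow = flow, flow_cv = flow_cv, flow_events = flow_events,
                 standard_2c = standard_2c,
                 diag_positions = diag_positions),
            class = "simulation_config")
}

# IUPAC consensus of two phased haplotypes; one-sided gaps become the
# full-length allele in the row, with the het run reported separately.
collapse_pair <- function(hap1, hap2) {
  a <- strsplit(hap1, "")[[1L]]; b <- strsplit(hap2, "")[[1L]]
  out <- character(length(a))
  het_gap <- logical(length(a))
  for (j in seq_along(a)) {
    if (a[j] == b[j]) out[j] <- a[j]
    else if (a[j] == "-") { out[j] <- b[j]; het_gap[j] <- TRUE }
    else if (b[j] == "-") { out[j] <- a[j]; het_gap[j] <- TRUE }
    else out[j] <- collapse_bases(c(a[j], b[j]))
  }
  list(row = paste(out, collapse = ""), het_runs = runs_of(het_gap))
}

#' Simulate a complete diagnostic study dataset
#'
#' Generates per-locus alignments, a taxon map (with het-indel sidecar),
#' and a truth table under the configured study design.  Parental founder
#' haplotypes differ at exactly the configured numbers of fixed
#' substitution columns and fixed indels; within-taxon variants are
#' single-substitution neighbours at non-diagnostic columns; F1 consensus
#' rows are column-wise IUPAC collapses of one haplotype from each parent;
#' apomictic clones are byte-identical; each candidate's chloroplast is
#' copied from its maternal parent.  Fully deterministic given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (mandatory).
#' @return list of class `simulated_dataset`: `alignments`, `taxa`
#'   ([taxon_map()]), `truth` (data.frame `sample_id`, `taxon`, `role`,
#'   `true_class`, `true_maternal`, `true_clone_group`), and `config`.
#' @export
simulate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (missing(seed)) stop("a seed is mandatory")
  with_seed(seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  loci <- config$loci
  n_loci <- nrow(loci)
  bases <- c("A", "C", "G", "T")

  # --- per-locus founder haplotypes and variant pools -----------------
  founders <- list()   # founders[[locus]] = list(A = chr, B = chr)
  pools <- list()      # pools[[locus]][[taxon]] = character vector of haps
  indel_events <- list()
  diag_pos <- list()
  for (i in seq_len(n_loci)) {
    lid <- loci$locus_id[i]
    len <- loci$length[i]
    bg <- sample(bases, len, replace = TRUE)
    ind_lens <- loci$indel_lengths[[i]]
    # place indel events first (non-overlapping, with a 1-column margin)
    taken <- logical(len)
    evs <- list()
    for (L in ind_lens) {
      repeat {
        s <- sample.int(len - L + 1L, 1L)
        rng <- s:(s + L - 1L)
        margin <- max(1L, s - 1L):min(len, s + L)
        if (!any(taken[margin])) break
      }
      taken[max(1L, s - 1L):min(len, s + L)] <- TRUE
      evs[[length(evs) + 1L]] <- c(start = s, end = s + L - 1L)
    }
    free <- which(!taken)
    k <- loci$n_substitutions[i]
    pos <- if (!is.null(config$diag_positions[[lid]])) {
      p <- as.integer(config$diag_positions[[lid]])
      if (any(p < 1L | p > len)) stop("diagnostic position outside locus ", lid)
      if (any(taken[p]))
        stop("config collision: diagnostic position inside an indel event at ", lid)
      sort(p)
    } else sort(sample(free, k))
    if (length(pos) != k) stop("could not place diagnostic positions at ", lid)

    fa <- bg; fb <- bg
    for (p in pos) {
      ab <- sample(bases, 2L)
      fa[p] <- ab[1L]; fb[p] <- ab[2L]
    }
    gapped_in <- character(length(evs))
    for (e in seq_along(evs)) {
      rng <- evs[[e]]["start"]:evs[[e]]["end"]
      gapped <- sample(c("A", "B"), 1L)
      if (gapped == "A") fa[rng] <- "-" else fb[rng] <- "-"
      gapped_in[e] <- gapped
    }
    founders[[lid]] <- list(A = paste(fa, collapse = ""),
                            B = paste(fb, collapse = ""))
    indel_events[[lid]] <- if (length(evs))
      data.frame(locus_id = lid,
                 start = vapply(evs, `[`, 0L, "start"),
                 end = vapply(evs, `[`, 0L, "end"),
                 present_in = ifelse(gapped_in == "A", "parentB", "parentA"),
                 stringsAsFactors = FALSE)
    else NULL
    diag_pos[[lid]] <- pos

    # within-taxon variant haplotypes (single-substitution neighbours)
    hap_key <- if (loci$compartment[i] == "chloroplast") "cp" else lid
    pools[[lid]] <- list()
    for (tx in c("parentA", "parentB")) {
      hc <- config$hap_counts$n[config$hap_counts$taxon == tx &
                                  config$hap_counts$locus_id == hap_key]
      hc <- if (length(hc)) hc[1L] else 1L
      founder <- founders[[lid]][[substr(tx, 7L, 7L)]]
      haps <- founder
      fc <- strsplit(founder, "")[[1L]]
      avail <- setdiff(free, pos)
      if (hc > 1L) {
        vpos <- sample(avail, hc - 1L)
        if (any(vpos %in% pos))
          stop("variant position collides with a diagnostic position")
        for (v in vpos) {
          alt <- sample(setdiff(bases, fc[v]), 1L)
          hv <- fc; hv[v] <- alt
          haps <- c(haps, paste(hv, collapse = ""))
        }
      }
      pools[[lid]][[tx]] <- haps
    }
  }

  # --- individuals ----------------------------------------------------
  is_cp <- loci$compartment == "chloroplast"
  nuc_ids <- loci$locus_id[!is_cp]
  cp_ids <- loci$locus_id[is_cp]

  rows <- lapply(stats::setNames(loci$locus_id, loci$locus_id),
                 function(...) list())
  het_rows <- list()
  truth <- list()

  # chloroplast haplotype of an individual: index into the taxon cp pool
  # (the same index across cp loci — they are co-inherited)
  cp_pool_size <- function(tx) length(pools[[cp_ids[1L]]][[tx]])

  add_sample <- function(sid, taxon, role, true_class, nuclear_haps,
                         cp_taxon, cp_idx, maternal) {
    for (l in nuc_ids) {
      pair <- nuclear_haps[[l]]
      cp_ <- collapse_pair(pair[1L], pair[2L])
      row <- cp_$row
      if (config$dropout_rate > 0 && pair[1L] != pair[2L]) {
        ch <- strsplit(row, "")[[1L]]
        het <- which(!is.na(iupac_order(ch)) & iupac_order(ch) == 2L)
        drop <- het[stats::runif(length(het)) < config$dropout_rate]
        for (j in drop) ch[j] <- sample(expand_iupac(ch[j]), 1L)
        row <- paste(ch, collapse = "")
      }
      rows[[l]][[sid]] <<- row
      if (nrow(cp_$het_runs))
        het_rows[[length(het_rows) + 1L]] <<- data.frame(
          sample_id = sid, locus_id = l,
          start = cp_$het_runs$start, end = cp_$het_runs$end,
          stringsAsFactors = FALSE)
    }
    for (l in cp_ids)
      rows[[l]][[sid]] <<- pools[[l]][[cp_taxon]][cp_idx]
    truth[[length(truth) + 1L]] <<- data.frame(
      sample_id = sid, taxon = taxon, role = role, true_class = true_class,
      true_maternal = maternal, stringsAsFactors = FALSE)
  }

  draw_parent_haps <- function(tx, idx, n_taxon) {
    # sample idx of a parental taxon: homozygous; the first (n-1) samples
    # carry the variant haplotypes so every configured haplotype is seen
    haps <- list()
    for (l in nuc_ids) {
      pool <- pools[[l]][[tx]]
      h <- if (idx < length(pool)) pool[idx + 1L] else pool[1L]
      haps[[l]] <- c(h, h)
    }
    haps
  }

  for (i in seq_len(config$n_parentA)) {
    cp_idx <- if (i < cp_pool_size("parentA")) i + 1L else 1L
    add_sample(sprintf("A%03d", i), "parentA", "parentA", "parentA",
               draw_parent_haps("parentA", i), "parentA",
               min(cp_idx, cp_pool_size("parentA")), "parentA")
  }
  for (i in seq_len(config$n_parentB)) {
    cp_idx <- if (i < cp_pool_size("parentB")) i + 1L else 1L
    add_sample(sprintf("B%03d", i), "parentB", "parentB", "parentB",
               draw_parent_haps("parentB", i), "parentB",
               min(cp_idx, cp_pool_size("parentB")), "parentB")
  }

  rand_haps <- function(tx) {
    h <- list()
    for (l in nuc_ids) {
      pool <- pools[[l]][[tx]]
      h[[l]] <- pool[sample.int(length(pool), 1L)]
    }
    h
  }
  ci <- 0L
  f1_a <- rand_haps("parentA"); f1_b <- rand_haps("parentB")
  f1_cp <- sample.int(cp_pool_size(config$maternal), 1L)
  for (i in seq_len(config$n_f1_clones)) {
    ci <- ci + 1L
    haps <- stats::setNames(lapply(nuc_ids, function(l)
      c(f1_a[[l]], f1_b[[l]])), nuc_ids)
    add_sample(sprintf("C%03d", ci), "candidate", "candidate", "F1", haps,
               config$maternal, f1_cp, config$maternal)
  }
  for (i in seq_len(config$n_f1_independent)) {
    ci <- ci + 1L
    ia <- rand_haps("parentA"); ib <- rand_haps("parentB")
    haps <- stats::setNames(lapply(nuc_ids, function(l)
      c(ia[[l]], ib[[l]])), nuc_ids)
    add_sample(sprintf("C%03d", ci), "candidate", "candidate", "F1", haps,
               config$maternal,
               sample.int(cp_pool_size(config$maternal), 1L),
               config$maternal)
  }
  make_backcross <- function(recurrent) {
    other <- if (recurrent == "parentA") "parentB" else "parentA"
    if (length(nuc_ids) < 2L)
      stop("backcross simulation needs >= 2 nuclear loci")
    repeat {
      from_other <- stats::runif(length(nuc_ids)) < 0.5
      if (any(from_other) && !all(from_other)) break
    }
    haps <- stats::setNames(lapply(seq_along(nuc_ids), function(j) {
      l <- nuc_ids[j]
      h1 <- pools[[l]][[recurrent]][
        sample.int(length(pools[[l]][[recurrent]]), 1L)]
      h2 <- if (from_other[j])
        pools[[l]][[other]][sample.int(length(pools[[l]][[other]]), 1L)]
      else pools[[l]][[recurrent]][
        sample.int(length(pools[[l]][[recurrent]]), 1L)]
      c(h1, h2)
    }), nuc_ids)
    haps
  }
  for (i in seq_len(config$n_backcross_A)) {
    ci <- ci + 1L
    add_sample(sprintf("C%03d", ci), "candidate", "candidate", "backcross_A",
               make_backcross("parentA"), "parentA",
               sample.int(cp_pool_size("parentA"), 1L), "parentA")
  }
  for (i in seq_len(config$n_backcross_B)) {
    ci <- ci + 1L
    add_sample(sprintf("C%03d", ci), "candidate", "candidate", "backcross_B",
               make_backcross("parentB"), "parentB",
               sample.int(cp_pool_size("parentB"), 1L), "parentB")
  }
  for (i in seq_len(config$n_parental_mislabeled)) {
    ci <- ci + 1L
    add_sample(sprintf("C%03d", ci), "parentA", "candidate", "parentA",
               draw_parent_haps("parentA", config$n_parentA + i), "parentA",
               1L, "parentA")
  }

  truth <- do.call(rbind, truth)
  # clone groups: identity of the full multilocus genotype
  geno_key <- vapply(truth$sample_id, function(s)
    paste(vapply(loci$locus_id, function(l) rows[[l]][[s]], ""),
          collapse = ";"), "")
  cand <- truth$role == "candidate"
  grp <- match(geno_key, unique(geno_key[cand]))
  truth$true_clone_group <- ifelse(cand, grp, NA_integer_)

  alignments <- lapply(stats::setNames(loci$locus_id, loci$locus_id),
                       function(l) locus_alignment(
                         l, loci$compartment[loci$locus_id == l],
                         unlist(rows[[l]])))
  assignments <- data.frame(sample_id = truth$sample_id,
                            taxon = truth$taxon, role = truth$role,
                            stringsAsFactors = FALSE)
  het <- if (length(het_rows)) do.call(rbind, het_rows) else NULL
  structure(list(alignments = alignments,
                 taxa = taxon_map(assignments, het),
                 truth = truth,
                 diagnostic_positions = diag_pos,
                 indel_events = do.call(rbind, indel_events),
                 config = config),
            class = "simulated_dataset")
}

#' Simulate a two-peak flow-cytometry event stream
#'
#' Events are drawn from two log-normally distributed peaks: the internal
#' standard at `standard_2c` and the sample at `sample_2c`, on an
#' arbitrary fluorescence scale of 100 channels per pg.
#'
#' @param sample_2c sample 2C DNA content, pg.
#' @param standard_2c internal-standard 2C (default 2.5 pg, chicken
#'   erythrocyte nuclei).
#' @param cv coefficient of variation of each peak (> 0).
#' @param n_events total events (>= 1000; default 10000, split evenly).
#' @param seed integer seed (mandatory).
#' @return data.frame `event_id`, `fl_area`.
#' @export
simulate_flow <- function(sample_2c, standard_2c = 2.5, cv = 0.03,
                          n_events = 10000L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(cv > 0, n_events >= 1000L, sample_2c > 0, standard_2c > 0)
  with_seed(seed, {
    n1 <- n_events %/% 2L
    n2 <- n_events - n1
    fl <- c(stats::rlnorm(n1, log(100 * sample_2c), sqrt(log(1 + cv^2))),
            stats::rlnorm(n2, log(100 * standard_2c), sqrt(log(1 + cv^2))))
    data.frame(event_id = seq_len(n_events), fl_area = fl)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the same FASTA/TSV dialects the pipeline consumes, plus the truth
#' table.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- sim$config$loci[c("locus_id", "compartment")]
  loci$file <- paste0(loci$locus_id, ".fasta")
  for (i in seq_len(nrow(loci)))
    write_locus_fasta(sim$alignments[[loci$locus_id[i]]],
                      file.path(dir, loci$file[i]))
  utils::write.table(loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  amap <- sim$taxa$assignments
  if (!is.null(sim$taxa$het_indels)) {
    amap$het_indels <- "het_indels.tsv"
    utils::write.table(sim$taxa$het_indels, file.path(dir, "het_indels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(amap, file.path(dir, "taxon_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
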